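## Seeded simulator of pooled amplicon sequencing: population genotypes,
## homeologous SNPs, and per-pool base counts with sequencing error.

.BASES <- c("A", "C", "G", "T")

## EMS alkylates G, so the canonical changes on the reference strand are
## G->A and C->T; other substitutions are the residual spectrum.
.emsAlt <- function(ref) c(A = NA, C = "T", G = "A", T = NA)[ref]

#' Simulation parameters
#'
#' Default values describe one 384-line screening unit of an EMS-mutagenized
#' allotetraploid population sequenced as 12 pools of 96 lines: a single
#' heterozygous mutant contributes 1 of 192 alleles to its pools (~0.5%
#' signal), sequencing error is well below that signal, homeologous SNPs sit
#' near 50% in every pool, and ~99% of induced changes are G/C-to-A/T
#' transitions with roughly three quarters of carriers heterozygous.
#'
#' @param nPlates number of 96-well plates (4 for the canonical design).
#' @param depth sequencing depth per pool position (reads).
#' @param errorRate total per-base sequencing error rate (split evenly over
#'   the three non-reference bases).
#' @param density induced mutations per kb per line (population average
#'   1/109 kb).
#' @param hetFraction fraction of planted mutations that are heterozygous.
#' @param spectrumFraction fraction of planted mutations that are G>A or C>T
#'   on the reference strand.
#' @param homeologFreq allele fraction of a fixed homeologous SNP (0.5 when
#'   the primers amplify both homeologs equally).
#' @param nHomeolog homeologous SNP positions planted per amplicon.
#' @param seed integer seed; all randomness in the simulator derives from it.
#' @return named list of validated parameters.
#' @export
simParams <- function(nPlates = 4L, depth = 5000L, errorRate = 5e-4,
                      density = 1 / 109, hetFraction = 317 / 432,
                      spectrumFraction = 0.99, homeologFreq = 0.5,
                      nHomeolog = 3L, seed = 1L) {
  p <- list(nPlates = as.integer(nPlates), depth = as.integer(depth),
            errorRate = errorRate, density = density,
            hetFraction = hetFraction, spectrumFraction = spectrumFraction,
            homeologFreq = homeologFreq, nHomeolog = as.integer(nHomeolog),
            seed = as.integer(seed))
  stopifnot(p$depth >= 1L, p$nPlates >= 1L,
            p$errorRate >= 0, p$errorRate <= 1,
            p$hetFraction >= 0, p$hetFraction <= 1,
            p$spectrumFraction >= 0, p$spectrumFraction <= 1,
            p$homeologFreq >= 0, p$homeologFreq <= 1,
            p$nHomeolog >= 0L)
  if (p$density < 0) stop("density must be >= 0")
  p
}

.normalizeAmplicons <- function(amplicons) {
  if (is(amplicons, "DNAStringSet")) amplicons <- as.character(amplicons)
  if (is.null(names(amplicons)) || any(names(amplicons) == ""))
    stop("amplicon sequences must be named")
  if (any(nchar(amplicons) == 0L)) stop("amplicon sequences must be non-empty")
  toupper(amplicons)
}

#' Simulate a mutagenized population
#'
#' Plants point mutations into the lines of a pooled population and fixes
#' homeologous SNP positions shared by all lines. Per line the mutation
#' count is Poisson with mean \code{density x total kb}; a
#' \code{spectrumFraction} share of mutations are G>A / C>T on the reference
#' strand (drawn uniformly over G/C sites) and the remainder are uniform
#' over the other substitutions; \code{hetFraction} of mutations are
#' heterozygous. Fully deterministic given \code{params$seed}.
#'
#' @param amplicons named character vector (or \code{DNAStringSet}) of
#'   reference amplicon sequences.
#' @param params see [simParams()].
#' @param nMutations optional exact total number of mutations to plant
#'   (lines drawn uniformly); overrides the Poisson model.
#' @return a list of class \code{SimTruth}: \code{mutations} (data.frame
#'   \code{line, amplicon, pos, ref, alt, zygosity}), \code{homeologs}
#'   (data.frame \code{amplicon, pos, ref, alt, freq}), \code{lines}
#'   (all line addresses) and \code{params}.
#' @examples
#' amp <- c(amp1 = paste(rep("ACGT", 100), collapse = ""))
#' truth <- simulatePopulation(amp, simParams(seed = 7), nMutations = 5)
#' truth$mutations
#' @export
simulatePopulation <- function(amplicons, params = simParams(),
                               nMutations = NULL) {
  amplicons <- .normalizeAmplicons(amplicons)
  set.seed(params$seed)
  grid <- expand.grid(column = .PLATE_COLS, row = .PLATE_ROWS,
                      plate = seq_len(params$nPlates),
                      stringsAsFactors = FALSE)
  lines <- lineAddress(grid$plate, grid$row, grid$column)

  chars <- lapply(amplicons, function(s) strsplit(s, "")[[1L]])
  posTab <- data.frame(
    amplicon = rep(names(amplicons), nchar(amplicons)),
    pos = unlist(lapply(nchar(amplicons), seq_len), use.names = FALSE),
    ref = unlist(chars, use.names = FALSE), stringsAsFactors = FALSE)

  ## homeologous SNPs first, excluded from mutation placement
  homeologs <- data.frame(amplicon = character(), pos = integer(),
                          ref = character(), alt = character(),
                          freq = numeric(), stringsAsFactors = FALSE)
  if (params$nHomeolog > 0L) {
    hl <- lapply(names(amplicons), function(a) {
      idx <- which(posTab$amplicon == a)
      pick <- sort(sample(idx, min(params$nHomeolog, length(idx))))
      ref <- posTab$ref[pick]
      alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L), "")
      data.frame(amplicon = a, pos = posTab$pos[pick], ref = ref, alt = alt,
                 freq = params$homeologFreq, stringsAsFactors = FALSE)
    })
    homeologs <- do.call(rbind, hl)
    rownames(homeologs) <- NULL
  }
  openIdx <- which(!paste(posTab$amplicon, posTab$pos) %in%
                     paste(homeologs$amplicon, homeologs$pos))

  totalKb <- sum(nchar(amplicons)) / 1000
  if (is.null(nMutations)) {
    perLine <- stats::rpois(length(lines), params$density * totalKb)
    carrier <- rep(lines, perLine)
  } else {
    carrier <- sample(lines, nMutations, replace = TRUE)
  }

  nMut <- length(carrier)
  mutations <- data.frame(line = character(), amplicon = character(),
                          pos = integer(), ref = character(),
                          alt = character(), zygosity = character(),
                          stringsAsFactors = FALSE)
  if (nMut > 0L) {
    gcIdx <- openIdx[posTab$ref[openIdx] %in% c("G", "C")]
    ems <- stats::runif(nMut) < params$spectrumFraction
    idx <- integer(nMut)
    alt <- character(nMut)
    for (i in seq_len(nMut)) {
      repeat {
        if (ems[i]) {
          j <- gcIdx[sample.int(length(gcIdx), 1L)]
          a <- unname(.emsAlt(posTab$ref[j]))
        } else {
          j <- openIdx[sample.int(length(openIdx), 1L)]
          choices <- setdiff(.BASES, c(posTab$ref[j],
                                       unname(.emsAlt(posTab$ref[j]))))
          a <- choices[sample.int(length(choices), 1L)]
        }
        ## one mutation per (line, site): redraw collisions
        key <- paste(carrier[i], posTab$amplicon[j], posTab$pos[j])
        prev <- paste(carrier[seq_len(i - 1L)],
                      posTab$amplicon[idx[seq_len(i - 1L)]],
                      posTab$pos[idx[seq_len(i - 1L)]])
        if (!key %in% prev) break
      }
      idx[i] <- j
      alt[i] <- a
    }
    zyg <- ifelse(stats::runif(nMut) < params$hetFraction, "het", "hom")
    mutations <- data.frame(line = carrier, amplicon = posTab$amplicon[idx],
                            pos = posTab$pos[idx], ref = posTab$ref[idx],
                            alt = alt, zygosity = zyg,
                            stringsAsFactors = FALSE)
    o <- order(mutations$amplicon, mutations$pos, mutations$line)
    mutations <- mutations[o, , drop = FALSE]
    rownames(mutations) <- NULL
  }
  structure(list(mutations = mutations, homeologs = homeologs,
                 lines = lines, amplicons = amplicons, params = params),
            class = "SimTruth")
}

#' Simulate per-pool base counts
#'
#' Draws, for every pool and amplicon position, a multinomial sample of
#' \code{params$depth} reads over the four bases. The expected fraction of a
#' mutant allele in a pool of \eqn{m} lines is \eqn{c/(2m)} where \eqn{c} is
#' the number of mutant allele copies the carrier contributes (1
#' heterozygous, 2 homozygous) — 1/192 (~0.5%) for one heterozygote in a
#' 96-line pool. Homeologous SNP positions receive their fixed allele
#' fraction in every pool, and each non-reference base receives
#' \code{errorRate/3}. Per-pool random streams are derived deterministically
#' from \code{params$seed}.
#'
#' @param truth a \code{SimTruth} from [simulatePopulation()].
#' @param design a \linkS4class{PoolingDesign} covering \code{truth$lines}.
#' @param params see [simParams()]; defaults to \code{truth$params}.
#' @return a \linkS4class{PoolCounts}.
#' @export
simulatePoolCounts <- function(truth, design, params = truth$params) {
  amplicons <- truth$amplicons
  chars <- lapply(amplicons, function(s) strsplit(s, "")[[1L]])
  rowdat <- data.frame(
    amplicon = rep(names(amplicons), nchar(amplicons)),
    pos = unlist(lapply(nchar(amplicons), seq_len), use.names = FALSE),
    ref = unlist(chars, use.names = FALSE), stringsAsFactors = FALSE)
  nPos <- nrow(rowdat)
  key <- paste(rowdat$amplicon, rowdat$pos)
  refRow <- match(rowdat$ref, .BASES)

  missing <- setdiff(truth$mutations$line, unlist(design@membership))
  if (length(missing))
    stop("truth lines not covered by the design: ",
         paste(missing, collapse = ", "))

  ## base probabilities common to all pools: error + homeologous SNPs
  baseProb <- matrix(0, nrow = 4L, ncol = nPos, dimnames = list(.BASES, NULL))
  baseProb[cbind(refRow, seq_len(nPos))] <- 1
  if (params$errorRate > 0) {
    baseProb <- baseProb * (1 - params$errorRate)
    baseProb <- baseProb + params$errorRate / 3
    baseProb[cbind(refRow, seq_len(nPos))] <-
      baseProb[cbind(refRow, seq_len(nPos))] - params$errorRate / 3
  }
  if (nrow(truth$homeologs)) {
    hIdx <- match(paste(truth$homeologs$amplicon, truth$homeologs$pos), key)
    hAlt <- match(truth$homeologs$alt, .BASES)
    for (k in seq_along(hIdx)) {
      f <- truth$homeologs$freq[k]
      baseProb[hAlt[k], hIdx[k]] <- baseProb[hAlt[k], hIdx[k]] + f
      baseProb[refRow[hIdx[k]], hIdx[k]] <-
        baseProb[refRow[hIdx[k]], hIdx[k]] - f
    }
  }

  poolIds <- design@poolIds
  counts <- lapply(.BASES, function(b)
    matrix(0L, nPos, length(poolIds),
           dimnames = list(NULL, as.character(poolIds))))
  names(counts) <- .BASES
  mutIdx <- match(paste(truth$mutations$amplicon, truth$mutations$pos), key)
  mutAlt <- match(truth$mutations$alt, .BASES)
  copies <- ifelse(truth$mutations$zygosity == "hom", 2L, 1L)

  for (j in seq_along(poolIds)) {
    id <- poolIds[j]
    members <- design@membership[[as.character(id)]]
    m <- length(members)
    prob <- baseProb
    inPool <- which(truth$mutations$line %in% members)
    for (k in inPool) {
      f <- copies[k] / (2 * m)
      prob[mutAlt[k], mutIdx[k]] <- prob[mutAlt[k], mutIdx[k]] + f
      prob[refRow[mutIdx[k]], mutIdx[k]] <-
        prob[refRow[mutIdx[k]], mutIdx[k]] - f
    }
    set.seed((params$seed * 1009L + j) %% 2147483647L)
    counts4 <- apply(prob, 2L, function(p)
      stats::rmultinom(1L, params$depth, p))
    for (b in 1:4) counts[[b]][, j] <- as.integer(counts4[b, ])
  }

  poolCounts(counts, rowdat, poolIds = poolIds,
             dimension = unname(design@dimension[as.character(poolIds)]))
}

#' Construct a PoolCounts object
#'
#' @param counts named list of four integer matrices (\code{A,C,G,T}),
#'   positions x pools.
#' @param rowdat data.frame with columns \code{amplicon}, \code{pos},
#'   \code{ref} describing the rows.
#' @param poolIds integer pool identifiers (columns).
#' @param dimension optional per-pool dimension labels.
#' @return a \linkS4class{PoolCounts}.
#' @export
poolCounts <- function(counts, rowdat, poolIds, dimension = NULL) {
  depth <- counts$A + counts$C + counts$G + counts$T
  cd <- S4Vectors::DataFrame(pool = as.integer(poolIds))
  if (!is.null(dimension)) cd$dimension <- dimension
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(A = counts$A, C = counts$C, G = counts$G, T = counts$T,
                  depth = depth),
    rowData = S4Vectors::DataFrame(rowdat), colData = cd)
  colnames(se) <- as.character(poolIds)
  new("PoolCounts", se)
}

#' Per-pool count table
#'
#' Extracts one pool's counts as the TSV-dialect data.frame
#' (\code{amplicon, pos, ref, nA, nC, nG, nT, depth}).
#'
#' @param counts a \linkS4class{PoolCounts}.
#' @param pool pool id.
#' @return data.frame, one row per position.
#' @export
poolTable <- function(counts, pool) {
  j <- match(as.character(pool), colnames(counts))
  if (is.na(j)) stop("pool ", pool, " not present")
  rd <- SummarizedExperiment::rowData(counts)
  data.frame(amplicon = rd$amplicon, pos = rd$pos, ref = rd$ref,
             nA = SummarizedExperiment::assay(counts, "A")[, j],
             nC = SummarizedExperiment::assay(counts, "C")[, j],
             nG = SummarizedExperiment::assay(counts, "G")[, j],
             nT = SummarizedExperiment::assay(counts, "T")[, j],
             depth = SummarizedExperiment::assay(counts, "depth")[, j],
             stringsAsFactors = FALSE)
}

.poolMpileupLines <- function(tab) {
  n <- nrow(tab)
  bases <- character(n)
  quals <- character(n)
  for (i in seq_len(n)) {
    cnt <- c(A = tab$nA[i], C = tab$nC[i], G = tab$nG[i], T = tab$nT[i])
    ref <- tab$ref[i]
    parts <- c(strrep(".", cnt[[ref]]),
               vapply(setdiff(.BASES, ref),
                      function(b) strrep(b, cnt[[b]]), ""))
    bases[i] <- paste(parts, collapse = "")
    quals[i] <- strrep("I", tab$depth[i])        # Phred 40 placeholder
    if (tab$depth[i] == 0L) {
      bases[i] <- "*"
      quals[i] <- "*"
    }
  }
  paste(tab$amplicon, tab$pos, tab$ref, tab$depth, bases, quals, sep = "\t")
}

#' Write a simulation fixture to disk
#'
#' Emits, for every pool, a count TSV and an mpileup-format text file (all
#' bases at a placeholder Phred 40), plus the truth tables, the design JSON
#' and the simulation parameters. Output is byte-reproducible for a given
#' truth/counts pair.
#'
#' @param truth a \code{SimTruth}.
#' @param counts a \linkS4class{PoolCounts}.
#' @param dir output directory (created if needed).
#' @param design optional \linkS4class{PoolingDesign} to write alongside.
#' @return character vector of written paths, invisibly.
#' @export
writeFixture <- function(truth, counts, dir, design = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (id in colnames(counts)) {
    tab <- poolTable(counts, id)
    pTsv <- file.path(dir, sprintf("pool%s.counts.tsv", id))
    utils::write.table(tab, pTsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pMp <- file.path(dir, sprintf("pool%s.mpileup", id))
    writeLines(.poolMpileupLines(tab), pMp)
    paths <- c(paths, pTsv, pMp)
  }
  tTsv <- file.path(dir, "truth.tsv")
  utils::write.table(truth$mutations, tTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hTsv <- file.path(dir, "homeologs.tsv")
  utils::write.table(truth$homeologs, hTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pJson <- file.path(dir, "params.json")
  jsonlite::write_json(truth$params, pJson, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, tTsv, hTsv, pJson)
  if (!is.null(design)) {
    dJson <- file.path(dir, "design.json")
    writeDesignJson(design, dJson)
    paths <- c(paths, dJson)
  }
  invisible(paths)
}
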