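## File formats and the end-to-end pipeline driver.

#' Read reference amplicon sequences
#'
#' Reads a FASTA file into a named, uppercase character vector of amplicon
#' sequences.
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  out
}

#' Write candidates as VCF
#'
#' Writes one VCF 4.2 record per candidate with INFO fields \code{POOLS}
#' (positive pools), \code{PVALS} and \code{FREQS} (per positive pool),
#' \code{LINESET} (decoded line addresses), \code{PF} (pooled frequency
#' over all pools), \code{EMS} (flag: G>A / C>T) and \code{REVIEW} (flag:
#' more positive pools than one full triple).
#'
#' @param candidates candidate data.frame from [callCandidates()].
#' @param reference named character vector of amplicon sequences (REF bases
#'   are checked against it), or NULL to skip the check and contig lengths.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCandidateVcf <- function(candidates, reference, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=scamprSeq")
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          nchar(reference)))
  hdr <- c(hdr,
    "##INFO=<ID=POOLS,Number=.,Type=String,Description=\"Positive pools\">",
    "##INFO=<ID=PVALS,Number=.,Type=Float,Description=\"Per positive pool one-sided t-test p-value\">",
    "##INFO=<ID=FREQS,Number=.,Type=Float,Description=\"Per positive pool substitution frequency\">",
    "##INFO=<ID=LINESET,Number=.,Type=String,Description=\"Decoded candidate line addresses\">",
    "##INFO=<ID=PF,Number=1,Type=Float,Description=\"Pooled substitution frequency over all pools\">",
    "##INFO=<ID=EMS,Number=0,Type=Flag,Description=\"G>A or C>T on the reference strand (EMS-consistent)\">",
    "##INFO=<ID=REVIEW,Number=0,Type=Flag,Description=\"More positive pools than one full triple\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  rows <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    if (!is.null(reference)) {
      refBase <- substr(reference[[cd$amplicon]], cd$pos, cd$pos)
      if (refBase != cd$ref)
        stop("REF mismatch at ", cd$amplicon, ":", cd$pos, ": reference has ",
             refBase, ", candidate has ", cd$ref)
    }
    info <- c(
      paste0("POOLS=", cd$pools),
      paste0("PVALS=", cd$pvals),
      paste0("FREQS=", cd$freqs),
      paste0("LINESET=", cd$lines),
      sprintf("PF=%.6g", cd$pooledFreq),
      if (isTRUE(cd$emsConsistent)) "EMS",
      if (isTRUE(cd$review)) "REVIEW")
    rows[i] <- paste(cd$amplicon, cd$pos, ".", cd$ref, cd$alt, ".", "PASS",
                     paste(info, collapse = ";"), sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a candidate review table
#'
#' Human-readable TSV mirroring the published candidate-list layout:
#' reference position, mutation (\code{ref>alt}), positive indexed pools,
#' and wells to validate.
#'
#' @param candidates candidate data.frame from [callCandidates()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCandidateTable <- function(candidates, path) {
  wells <- vapply(candidates$lines, function(l) {
    if (!nzchar(l)) return("")
    p <- parseAddress(strsplit(l, ",")[[1L]])
    paste0("Plate ", p$plate[1L], " - ", paste(p$well, collapse = ", "))
  }, "", USE.NAMES = FALSE)
  out <- data.frame(
    amplicon = candidates$amplicon,
    position = candidates$pos,
    mutation = paste0(candidates$ref, ">", candidates$alt),
    positive_pools = candidates$pools,
    wells_to_validate = wells,
    ems_consistent = candidates$emsConsistent,
    review = candidates$review, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects paths and thresholds for [runPipeline()] with the package
#' defaults: base quality > 20, per-pool alpha 0.05, minimum filtered depth
#' 100, homeolog thresholds 0.2 / 0.9, 200 bp amplicon-edge exclusion and a
#' 1,132 Mb genome for density statistics.
#'
#' @param design path to a design JSON (or a \linkS4class{PoolingDesign}).
#' @param countFiles named character vector (pool id -> count TSV path).
#' @param pileupFiles named character vector (pool id -> mpileup path);
#'   alternative to \code{countFiles}.
#' @param reference path to the reference FASTA (or named sequences).
#' @param geneModelFile optional feature TSV for effect annotation.
#' @param outDir output directory.
#' @param minBaseQuality,alpha,minDepth,minAltFreq,homeologMinFreq,homeologPoolFraction,emsOnly
#'   caller thresholds, see [callCandidates()] and [countsFromPileup()].
#' @param edgeExclusion,genomeSizeMb density-statistic settings.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(design, countFiles = NULL, pileupFiles = NULL,
                      reference = NULL, geneModelFile = NULL,
                      outDir = ".", minBaseQuality = 20L, alpha = 0.05,
                      minDepth = 100L, minAltFreq = NULL,
                      homeologMinFreq = 0.2, homeologPoolFraction = 0.9,
                      emsOnly = FALSE, edgeExclusion = 200L,
                      genomeSizeMb = 1132) {
  cfg <- as.list(environment())
  if (is.null(cfg$countFiles) && is.null(cfg$pileupFiles))
    stop("config error: one of countFiles or pileupFiles is required")
  for (f in c(cfg$countFiles, cfg$pileupFiles, cfg$geneModelFile,
              if (is.character(cfg$design)) cfg$design,
              if (is.character(cfg$reference)) cfg$reference))
    if (!file.exists(f)) stop("config error: missing file: ", f)
  structure(cfg, class = "RunConfig")
}

.stage <- function(name, ...) message("[", name, "] ", ...)

#' Run the detection pipeline
#'
#' Executes counts -> frequencies -> background/test -> candidate calls ->
#' (optional) effect annotation -> reports, logging record counts per
#' stage. Deterministic for fixed inputs: reports carry no timestamps.
#'
#' @param config a \code{RunConfig}, see [runConfig()].
#' @return list with \code{candidates}, \code{homeologs}, \code{counts} and
#'   the written \code{paths}, invisibly.
#' @export
runPipeline <- function(config) {
  design <- if (is(config$design, "PoolingDesign")) config$design
            else readDesignJson(config$design)
  .stage("design", "scheme '", design@schemeId, "', ",
         length(design@poolIds), " pools")
  if (!is.null(config$countFiles)) {
    tables <- lapply(config$countFiles, readCountsTsv)
  } else {
    tables <- lapply(config$pileupFiles, countsFromPileup,
                     minBaseQuality = config$minBaseQuality)
  }
  counts <- assemblePoolCounts(tables, dimension = design)
  .stage("counts", nrow(counts), " positions x ", ncol(counts), " pools")
  candidates <- callCandidates(
    counts, design, alpha = config$alpha, minDepth = config$minDepth,
    minAltFreq = config$minAltFreq,
    homeologMinFreq = config$homeologMinFreq,
    homeologPoolFraction = config$homeologPoolFraction,
    emsOnly = config$emsOnly)
  homeologs <- attr(candidates, "homeologs")
  .stage("call", nrow(candidates), " candidates, ", nrow(homeologs),
         " homeolog positions")
  reference <- if (is.character(config$reference)) readFasta(config$reference)
               else config$reference
  if (!is.null(config$geneModelFile) && nrow(candidates)) {
    eff <- character(nrow(candidates))
    for (a in unique(candidates$amplicon)) {
      model <- readGeneModelTsv(config$geneModelFile, a, reference[[a]])
      sel <- candidates$amplicon == a
      eff[sel] <- annotateEffect(model, candidates$pos[sel],
                                 candidates$ref[sel], candidates$alt[sel])
    }
    candidates$effect <- eff
    .stage("annotate", nrow(candidates), " records")
  }
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  paths <- c(
    vcf = writeCandidateVcf(candidates, reference,
                            file.path(config$outDir, "candidates.vcf")),
    tsv = writeCandidateTable(candidates,
                              file.path(config$outDir, "candidates.tsv")))
  hPath <- file.path(config$outDir, "homeologs.tsv")
  utils::write.table(homeologs, hPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, homeologs = hPath)
  .stage("report", "wrote ", paste(basename(paths), collapse = ", "))
  invisible(list(candidates = candidates, homeologs = homeologs,
                 counts = counts, paths = paths))
}
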