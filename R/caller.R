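## Candidate mutation calling: per-pool background noise model, one-sided
## t-test, three-pool coincidence, homeologous-SNP discrimination.

#' EMS consistency of a substitution
#'
#' EMS alkylates guanine, so induced changes are G>A or C>T on the
#' reference strand; anything else (e.g. A>G) is inconsistent with EMS
#' mutagenesis.
#'
#' @param ref,alt reference and alternate base (vectorised).
#' @return logical vector.
#' @examples
#' emsConsistent(c("C", "G", "A"), c("T", "A", "G"))   # TRUE TRUE FALSE
#' @export
emsConsistent <- function(ref, alt) {
  if (any(ref == alt)) stop("ref and alt must differ")
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Homeologous-SNP classification
#'
#' Fixed differences between homeologous gene copies of an allopolyploid
#' appear in every pool at high frequency (~50% when both homeologs amplify
#' equally), unlike an induced mutation, which is confined to the three
#' pools carrying its line. A substitution is flagged homeolog when its
#' frequency reaches \code{minFreq} in at least \code{poolFraction} of the
#' pools with data.
#'
#' @param freqs numeric vector of the substitution's frequency in each pool
#'   (NA = no data).
#' @param minFreq frequency threshold (default 0.2).
#' @param poolFraction required fraction of pools at or above the threshold
#'   (default 0.9).
#' @return logical flag.
#' @examples
#' classifyHomeolog(rep(0.5, 12))               # TRUE
#' classifyHomeolog(c(rep(0.005, 3), rep(0, 9)))  # FALSE
#' @export
classifyHomeolog <- function(freqs, minFreq = 0.2, poolFraction = 0.9) {
  ok <- !is.na(freqs)
  if (!any(ok)) stop("no pool has data")
  sum(freqs[ok] >= minFreq) / sum(ok) >= poolFraction
}

#' Background noise model for one pool and substitution type
#'
#' Sequencing-error noise is estimated empirically: the mean and standard
#' deviation of the substitution's frequency over all other positions with
#' the same reference base in the same pool (homeolog-flagged and excluded
#' positions removed).
#'
#' @param freqTable long frequency table from [baseFrequencies()].
#' @param pool pool id.
#' @param ref,alt substitution type (reference and alternate base).
#' @param excludePos positions to exclude (e.g. the focal position and
#'   known homeolog sites), as positions or \code{"amplicon:pos"} keys.
#' @param amplicon optional amplicon to restrict to.
#' @return list with \code{mean}, \code{sd} (sample sd), \code{n}.
#' @export
fitBackground <- function(freqTable, pool, ref, alt, excludePos = integer(),
                          amplicon = NULL) {
  sel <- freqTable$pool == pool & freqTable$ref == ref &
    freqTable$alt == alt & !freqTable$noData
  if (!is.null(amplicon)) sel <- sel & freqTable$amplicon == amplicon
  if (is.character(excludePos)) {
    sel <- sel & !paste(freqTable$amplicon, freqTable$pos, sep = ":") %in%
      excludePos
  } else {
    sel <- sel & !freqTable$pos %in% excludePos
  }
  x <- freqTable$freq[sel]
  if (length(x) < 2L)
    stop("need >= 2 background positions, have ", length(x))
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' One-sided test of a focal frequency against background noise
#'
#' Upper-tail prediction-interval style t-test of whether the focal
#' substitution frequency exceeds the background sequencing-error noise:
#' \deqn{t = (f - \bar{x}) / (s' \sqrt{1 + 1/n}), \quad df = n - 1}
#' with \eqn{s' = \max(s, s_{floor})}. The floor (one read at the focal
#' filtered depth, \eqn{1/(2 d)}) keeps the statistic finite when the
#' background is all zeros.
#'
#' @param freq focal frequency.
#' @param background list with \code{mean}, \code{sd}, \code{n} (see
#'   [fitBackground()]).
#' @param depth focal filtered depth, used for the sd floor; \code{NULL}
#'   disables the floor.
#' @return one-sided upper-tail p-value in [0, 1].
#' @examples
#' bg <- list(mean = 2e-4, sd = 2e-4, n = 1000)
#' testPosition(0.005, bg, depth = 5000)
#' @export
testPosition <- function(freq, background, depth = NULL) {
  sdFloor <- if (is.null(depth)) 0 else 1 / (2 * depth)
  s <- max(background$sd, sdFloor)
  n <- background$n
  if (s == 0) {
    return(if (freq > background$mean) 0
           else if (freq < background$mean) 1 else 0.5)
  }
  t <- (freq - background$mean) / (s * sqrt(1 + 1 / n))
  stats::pt(t, df = n - 1, lower.tail = FALSE)
}

## Leave-one-out background mean/sd/n per focal position, from per-pool
## column sums over the valid background positions of one substitution type.
.looBackground <- function(F, ok) {
  nBg <- matrix(colSums(ok), nrow(F), ncol(F), byrow = TRUE)
  s1 <- matrix(colSums(ifelse(ok, F, 0)), nrow(F), ncol(F), byrow = TRUE)
  s2 <- matrix(colSums(ifelse(ok, F^2, 0)), nrow(F), ncol(F), byrow = TRUE)
  inBg <- ok
  n <- ifelse(inBg, nBg - 1L, nBg)
  m <- ifelse(inBg, (s1 - ifelse(inBg, F, 0)) / pmax(n, 1L), s1 / pmax(n, 1L))
  ss <- ifelse(inBg, s2 - F^2, s2)
  v <- (ss - n * m^2) / pmax(n - 1L, 1L)
  list(n = n, mean = m, var = pmax(v, 0))
}

#' Call candidate mutations
#'
#' Implements the pooled-amplicon candidate rule: a substitution at a
#' position is screened as a potential mutant when its frequency in a pool
#' reaches the low-frequency signal expected of a single mutant line
#' (\code{minAltFreq}), verified by a one-sided t-test against the per-pool,
#' per-substitution-type background noise (see [testPosition()]), and
#' emitted as a candidate only when the set of positive pools contains a
#' full triple — one column, one row and one plate pool — which the design
#' then decodes to a small set of candidate lines. Positions whose
#' substitution is present at high frequency in (nearly) all pools are
#' homeologous-SNP sites and are never emitted. Candidates are annotated,
#' not filtered, by EMS consistency unless \code{emsOnly}.
#'
#' @param counts a \linkS4class{PoolCounts} covering all pools of the
#'   design.
#' @param design the \linkS4class{PoolingDesign}.
#' @param alpha per-pool significance level (default 0.05).
#' @param minDepth minimum filtered depth for a pool position to be tested
#'   (default 100).
#' @param minAltFreq low-frequency screen threshold; default half the
#'   expected one-heterozygote signal, \code{1/(4 * pool size)} (= 1/384 ~
#'   0.26% for 96-line pools, against the ~0.5% expected signal).
#' @param homeologMinFreq,homeologPoolFraction homeolog classification
#'   thresholds (see [classifyHomeolog()]); \code{homeologMinFreq} also
#'   bounds the pooled candidate frequency from above (induced mutations
#'   are expected near ~1%, far below homeolog frequencies).
#' @param emsOnly if TRUE, drop candidates that are not G>A / C>T.
#' @return data.frame of candidates: \code{amplicon, pos, ref, alt, pools}
#'   (positive pools, \code{","}-separated), \code{pvals}, \code{freqs}
#'   (same order as \code{pools}), \code{lines} (decoded addresses),
#'   \code{nLines}, \code{pooledFreq}, \code{emsConsistent}, \code{review}
#'   (TRUE when more pools than one full triple were positive). Attribute
#'   \code{"homeologs"} carries the homeolog-flagged substitutions as a
#'   data.frame.
#' @export
callCandidates <- function(counts, design, alpha = 0.05, minDepth = 100L,
                           minAltFreq = NULL,
                           homeologMinFreq = 0.2,
                           homeologPoolFraction = 0.9, emsOnly = FALSE) {
  ids <- colnames(counts)
  missing <- setdiff(as.character(design@poolIds), ids)
  if (length(missing))
    stop("pools missing from input: ", paste(missing, collapse = ", "))
  if (is.null(minAltFreq)) {
    poolSize <- length(design@membership[[1L]])
    minAltFreq <- 1 / (4 * poolSize)
  }
  rd <- SummarizedExperiment::rowData(counts)
  depth <- SummarizedExperiment::assay(counts, "depth")
  dims <- design@dimension[ids]
  nDim <- length(unique(design@dimension))

  cand <- list()
  homeo <- list()
  for (refBase in .BASES) {
    rows <- which(rd$ref == refBase)
    if (length(rows) < 3L) next
    D <- depth[rows, , drop = FALSE]
    for (altBase in setdiff(.BASES, refBase)) {
      Fmat <- SummarizedExperiment::assay(counts, altBase)[rows, ,
                                                           drop = FALSE] / D
      valid <- D >= minDepth & is.finite(Fmat)
      hasData <- rowSums(valid) > 0L
      isHom <- hasData &
        rowSums(Fmat >= homeologMinFreq & valid) >=
          homeologPoolFraction * rowSums(valid)
      if (any(isHom))
        homeo[[paste(refBase, altBase)]] <- data.frame(
          amplicon = rd$amplicon[rows[isHom]], pos = rd$pos[rows[isHom]],
          ref = refBase, alt = altBase, stringsAsFactors = FALSE)
      ok <- valid & !isHom            # background positions per pool
      if (all(colSums(ok) < 3L)) next
      bg <- .looBackground(Fmat, ok)
      sdAdj <- pmax(sqrt(bg$var), 1 / (2 * D))
      tstat <- (Fmat - bg$mean) / (sdAdj * sqrt(1 + 1 / pmax(bg$n, 1L)))
      p <- stats::pt(tstat, df = pmax(bg$n - 1L, 1L), lower.tail = FALSE)
      positive <- valid & !isHom & p <= alpha & Fmat >= minAltFreq &
        bg$n >= 2L
      hits <- which(rowSums(positive) > 0L)
      for (i in hits) {
        posIds <- ids[positive[i, ]]
        posDims <- dims[posIds]
        if (length(unique(posDims)) < nDim) next
        totAlt <- sum(Fmat[i, ] * D[i, ], na.rm = TRUE)
        pooledFreq <- totAlt / sum(D[i, ])
        if (pooledFreq >= homeologMinFreq) next
        review <- length(posIds) > nDim
        linesHit <- tryCatch({
          perDim <- split(posIds, posDims)
          Reduce(intersect, lapply(perDim, function(pp)
            unique(unlist(design@membership[pp]))))
        }, error = function(e) character())
        if (!review && length(posIds) == nDim)
          linesHit <- decodePools(design, as.integer(posIds))
        cand[[length(cand) + 1L]] <- data.frame(
          amplicon = rd$amplicon[rows[i]], pos = rd$pos[rows[i]],
          ref = refBase, alt = altBase,
          pools = paste(posIds, collapse = ","),
          pvals = paste(signif(p[i, positive[i, ]], 4L), collapse = ","),
          freqs = paste(signif(Fmat[i, positive[i, ]], 4L), collapse = ","),
          lines = paste(linesHit, collapse = ","),
          nLines = length(linesHit), pooledFreq = pooledFreq,
          emsConsistent = emsConsistent(refBase, altBase),
          review = review, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(cand)) do.call(rbind, cand) else
    data.frame(amplicon = character(), pos = integer(), ref = character(),
               alt = character(), pools = character(), pvals = character(),
               freqs = character(), lines = character(), nLines = integer(),
               pooledFreq = numeric(), emsConsistent = logical(),
               review = logical(), stringsAsFactors = FALSE)
  if (emsOnly) out <- out[out$emsConsistent, , drop = FALSE]
  out <- out[order(out$amplicon, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "homeologs") <- if (length(homeo)) {
    h <- do.call(rbind, homeo)
    rownames(h) <- NULL
    h[order(h$amplicon, h$pos, h$alt), , drop = FALSE]
  } else {
    data.frame(amplicon = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  }
  out
}
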