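## TILLING population statistics: mutation density with amplicon-edge
## exclusion, per-genome extrapolation, substitution spectrum, per-line
## distribution.

#' Mutation density of one amplicon screen
#'
#' Density is reported field-style as "1 mutation per N kb screened", with
#' the screened length per line reduced by \code{edgeExclusion} bp because
#' mutations cannot be detected near the PCR primers (100 bp at each end):
#' \deqn{N = lines \times (size - edge) / mutations / 1000}
#' \code{N} is rounded to the nearest integer kb for the label; the
#' unrounded value is retained.
#'
#' @param mutations number of unique mutations found.
#' @param linesScreened number of lines screened.
#' @param ampliconBp amplicon length in bp.
#' @param edgeExclusion unscreenable bp per amplicon (default 200).
#' @return list with \code{kbPerMutation} (unrounded; NA if no mutations),
#'   \code{label} (e.g. \code{"1/56"}; \code{"none found"} if no
#'   mutations), and \code{screenedBp}.
#' @examples
#' mutationDensity(38, 1536, 1583)$label   # "1/56"
#' @export
mutationDensity <- function(mutations, linesScreened, ampliconBp,
                            edgeExclusion = 200L) {
  if (ampliconBp <= edgeExclusion)
    stop("amplicon size must exceed the edge exclusion")
  screenedBp <- linesScreened * (ampliconBp - edgeExclusion)
  if (mutations == 0L)
    return(list(kbPerMutation = NA_real_, label = "none found",
                screenedBp = screenedBp))
  kb <- screenedBp / mutations / 1000
  list(kbPerMutation = kb, label = sprintf("1/%d", round(kb)),
       screenedBp = screenedBp)
}

#' Aggregate mutation density and genome projection
#'
#' Pools amplicon screens: the aggregate density is total screened kb over
#' total mutations (each amplicon reduced by the edge exclusion), and the
#' per-genome projection is \code{genome size / aggregate density}.
#'
#' @param screens data.frame with columns \code{amplicon}, \code{mutations},
#'   \code{linesScreened}, \code{ampliconBp} (see [readScreens()]).
#' @param edgeExclusion unscreenable bp per amplicon (default 200).
#' @param genomeSizeMb genome size in Mb for the projection (default 1,132
#'   Mb, the estimated allotetraploid B. napus genome).
#' @return list: \code{perAmplicon} (screens with \code{kbPerMutation},
#'   \code{density} label and \code{screenedBp} added), \code{totalMutations},
#'   \code{screenedBp}, \code{aggregateKb}, \code{aggregateLabel},
#'   \code{mutationsPerGenome}, plus \code{meanMutations} and
#'   \code{meanAmpliconBp} convenience summaries.
#' @export
aggregateDensity <- function(screens, edgeExclusion = 200L,
                             genomeSizeMb = 1132) {
  if (!nrow(screens)) stop("no screens")
  per <- lapply(seq_len(nrow(screens)), function(i)
    mutationDensity(screens$mutations[i], screens$linesScreened[i],
                    screens$ampliconBp[i], edgeExclusion))
  perAmplicon <- cbind(screens, data.frame(
    kbPerMutation = vapply(per, function(x) x$kbPerMutation, 0),
    density = vapply(per, function(x) x$label, ""),
    screenedBp = vapply(per, function(x) x$screenedBp, 0)))
  totalMutations <- sum(screens$mutations)
  screenedBp <- sum(perAmplicon$screenedBp)
  if (totalMutations == 0L) stop("no mutations in any screen")
  aggregateKb <- screenedBp / totalMutations / 1000
  list(perAmplicon = perAmplicon, totalMutations = totalMutations,
       screenedBp = screenedBp, aggregateKb = aggregateKb,
       aggregateLabel = sprintf("1/%d", round(aggregateKb)),
       mutationsPerGenome = genomeSizeMb * 1000 / aggregateKb,
       meanMutations = mean(screens$mutations),
       meanAmpliconBp = mean(screens$ampliconBp))
}

## strand-collapsed substitution class
.substitutionClass <- function(ref, alt) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || !ref %in% .BASES ||
      !alt %in% .BASES)
    return("indel")
  key <- paste0(ref, alt)
  switch(key,
         CT = , GA = "GC>AT",
         AG = , TC = "AT>GC",
         AC = , TG = "AT>CG",
         GT = , CA = "GC>TA",
         GC = , CG = "GC>CG",
         AT = , TA = "AT>TA",
         stop("ref and alt must differ: ", key))
}

#' Substitution spectrum
#'
#' Tabulates mutations into strand-collapsed substitution classes (C>T and
#' G>A are one class, etc.; multi-base records count as \code{indel}) and
#' reports the share of G/C-to-A/T transitions — the EMS signature — as an
#' integer percentage.
#'
#' @param records data.frame with columns \code{ref} and \code{alt}.
#' @return list with \code{classCounts} (named integer vector),
#'   \code{total}, and \code{percentGCtoAT}.
#' @examples
#' recs <- data.frame(ref = c("C", "G", "A"), alt = c("T", "A", "G"))
#' mutationSpectrum(recs)$percentGCtoAT
#' @export
mutationSpectrum <- function(records) {
  cls <- vapply(seq_len(nrow(records)), function(i)
    .substitutionClass(toupper(records$ref[i]), toupper(records$alt[i])), "")
  lev <- c("GC>AT", "AT>GC", "GC>TA", "GC>CG", "AT>CG", "AT>TA", "indel")
  counts <- table(factor(cls, levels = lev))
  total <- length(cls)
  list(classCounts = stats::setNames(as.integer(counts), lev), total = total,
       percentGCtoAT = if (total) round(100 * counts[["GC>AT"]] / total)
                       else NA_real_)
}

#' Mutations-per-line distribution
#'
#' Histogram of how many mutations each line carries, and the number of
#' lines carrying at least one.
#'
#' @param records data.frame with a \code{line} column (one row per
#'   mutation), or \code{NULL} when \code{histogram} is supplied.
#' @param totalLines optional population size, to include the zero bin.
#' @param histogram optional pre-tabulated named vector (names = mutations
#'   per line, values = number of lines) used instead of \code{records}.
#' @return list: \code{histogram} (named integer vector over 0..max when
#'   the zero bin is known), \code{linesWithAtLeastOne},
#'   \code{totalAssignments} (\eqn{\sum_k k \cdot n_k}).
#' @examples
#' perLineDistribution(histogram = c("0" = 1467, "1" = 279, "2" = 58,
#'                                   "3" = 5, "4" = 1))
#' @export
perLineDistribution <- function(records = NULL, totalLines = NULL,
                                histogram = NULL) {
  if (is.null(histogram)) {
    perLine <- table(records$line)
    ks <- if (length(perLine)) seq_len(max(perLine)) else integer()
    histogram <- stats::setNames(
      vapply(ks, function(k) sum(perLine == k), 0L), as.character(ks))
    if (!is.null(totalLines)) {
      zero <- totalLines - length(perLine)
      histogram <- c(stats::setNames(as.integer(zero), "0"), histogram)
    }
  } else {
    histogram <- stats::setNames(as.integer(histogram), names(histogram))
  }
  k <- as.integer(names(histogram))
  list(histogram = histogram,
       linesWithAtLeastOne = sum(histogram[k >= 1L]),
       totalAssignments = sum(k * histogram))
}

#' Screen bookkeeping check
#'
#' Compares the number of mutation-to-line assignments implied by a
#' per-line histogram with an independently reported count of unique
#' mutations; a non-zero discrepancy flags inconsistent bookkeeping between
#' the two summaries rather than being silently reconciled.
#'
#' @param histogram named vector, mutations-per-line -> number of lines.
#' @param uniqueMutations independently reported unique mutation count.
#' @return list with \code{assignments}, \code{uniqueMutations} and
#'   \code{discrepancy} (\code{uniqueMutations - assignments}).
#' @export
screenBookkeeping <- function(histogram, uniqueMutations) {
  k <- as.integer(names(histogram))
  assignments <- sum(k * as.integer(histogram))
  list(assignments = assignments, uniqueMutations = uniqueMutations,
       discrepancy = uniqueMutations - assignments)
}

#' Packaged screen-summary fixtures
#'
#' \code{readScreens} reads an amplicon screen summary TSV (columns
#' \code{amplicon, gene, mutations, linesScreened, ampliconBp} and
#' optionally \code{densityPrinted}, the density label as published).
#' \code{scamprFixture} resolves a packaged fixture file under
#' \code{extdata}: the 26-amplicon screen summary of the canola EMS
#' population (\code{"tilling_screens.tsv"}), its per-line mutation
#' histogram (\code{"mutations_per_line.tsv"}), effect-group counts
#' (\code{"effect_group_counts.tsv"}), the substitution-spectrum counts
#' (\code{"spectrum_counts.tsv"}), and the pooled-sequencing candidate list
#' with positive pools and validated wells (\code{"ngs_candidates.tsv"}).
#'
#' @param path TSV file path.
#' @return \code{readScreens}: data.frame. \code{scamprFixture}: file path.
#' @export
readScreens <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' @rdname readScreens
#' @param name fixture file name.
#' @export
scamprFixture <- function(name) {
  p <- system.file("extdata", name, package = "scamprSeq", mustWork = TRUE)
  p
}
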