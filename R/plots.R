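## Per-pool substitution-frequency profiles (read depth on top, one panel
## per substitution type), the standard visual check that true mutations
## spike in exactly three pools while homeologous SNPs ride high everywhere.

#' Plot per-pool frequency profiles
#'
#' Draws read depth across the amplicon and, below it, the per-pool
#' frequency of each requested substitution type at every position. Induced
#' mutations appear as isolated spikes shared by the three pools carrying
#' the mutant line; homeologous SNPs appear as high-frequency columns in
#' all pools.
#'
#' @param counts a \linkS4class{PoolCounts}.
#' @param amplicon amplicon to plot (default: first).
#' @param substitutions substitution types to panel (default C>T, G>A,
#'   A>G).
#' @param highlightPools optional pool ids drawn in colour.
#' @param ylim frequency axis limit (default 0.05; homeolog columns are
#'   clipped so the low-frequency signal stays visible).
#' @return invisibly, the long frequency table used for plotting.
#' @export
plotFrequencyProfiles <- function(counts, amplicon = NULL,
                                  substitutions = c("C>T", "G>A", "A>G"),
                                  highlightPools = NULL, ylim = 0.05) {
  rd <- SummarizedExperiment::rowData(counts)
  if (is.null(amplicon)) amplicon <- rd$amplicon[1L]
  sel <- rd$amplicon == amplicon
  pos <- rd$pos[sel]
  depth <- SummarizedExperiment::assay(counts, "depth")[sel, , drop = FALSE]
  old <- graphics::par(mfrow = c(length(substitutions) + 1L, 1L),
                       mar = c(2.2, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::matplot(pos, depth, type = "l", lty = 1L, col = "grey40",
                    xlab = "", ylab = "read depth", main = amplicon)
  freqTab <- baseFrequencies(counts)
  freqTab <- freqTab[freqTab$amplicon == amplicon, , drop = FALSE]
  for (sub in substitutions) {
    parts <- strsplit(sub, ">", fixed = TRUE)[[1L]]
    ft <- freqTab[freqTab$ref == parts[1L] & freqTab$alt == parts[2L], ,
                  drop = FALSE]
    graphics::plot(NA, xlim = range(pos), ylim = c(0, ylim), xlab = "",
                   ylab = "frequency", main = sub)
    for (id in unique(ft$pool)) {
      fp <- ft[ft$pool == id, ]
      hl <- !is.null(highlightPools) && id %in% as.character(highlightPools)
      graphics::points(fp$pos, pmin(fp$freq, ylim),
                       pch = if (hl) 19L else 1L, cex = 0.4,
                       col = if (hl) "red" else grDevices::grey(0.5, 0.5))
    }
  }
  invisible(freqTab)
}
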