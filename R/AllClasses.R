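#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Tri-dimensional pooling design
#'
#' A \code{PoolingDesign} records how the lines of a mutagenized population,
#' arrayed on 96-well plates, are combined into overlapping DNA pools along
#' three dimensions (column blocks, row pairs, whole plates). Every line is a
#' member of exactly one pool per dimension, so the set of pools in which a
#' mutation is observed (one per dimension) intersects down to a small set of
#' candidate lines.
#'
#' @slot schemeId identifier of the registered layout the design was built
#'   from (e.g. \code{"canonical384"}).
#' @slot nPlates number of 96-well plates covered by the design.
#' @slot poolIds integer pool identifiers (1-based, as printed on pooled
#'   sequencing libraries).
#' @slot dimension named character vector giving each pool's dimension
#'   (\code{"column"}, \code{"row"} or \code{"plate"}); names are pool ids.
#' @slot membership named list mapping pool id to the character vector of
#'   line addresses (see [lineAddress()]) it contains.
#'
#' @seealso [buildDesign()], [poolsForLine()], [decodePools()],
#'   [validateDesign()]
#' @export
setClass("PoolingDesign",
  representation(
    schemeId   = "character",
    nPlates    = "integer",
    poolIds    = "integer",
    dimension  = "character",
    membership = "list"
  )
)

setValidity("PoolingDesign", function(object) {
  msg <- character()
  if (length(object@poolIds) != length(object@membership) ||
      length(object@poolIds) != length(object@dimension))
    msg <- c(msg, "poolIds, dimension and membership must have equal length")
  if (!all(names(object@membership) == as.character(object@poolIds)))
    msg <- c(msg, "membership names must equal poolIds")
  if (!all(object@dimension %in% c("column", "row", "plate")))
    msg <- c(msg, "dimensions must be 'column', 'row' or 'plate'")
  if (length(msg)) msg else TRUE
})

#' Per-pool, per-position base counts
#'
#' \code{PoolCounts} holds quality-filtered A/C/G/T counts for every amplicon
#' position in every pool, as a \linkS4class{SummarizedExperiment}: rows are
#' (amplicon, position) pairs with the reference base in \code{rowData};
#' columns are pools; assays are the four base-count matrices plus the
#' filtered depth.
#'
#' @seealso [poolCounts()], [countsFromPileup()], [baseFrequencies()],
#'   [callCandidates()]
#' @export
setClass("PoolCounts", contains = "SummarizedExperiment")

setValidity("PoolCounts", function(object) {
  msg <- character()
  need <- c("A", "C", "G", "T", "depth")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("amplicon", "pos", "ref") %in% colnames(rd)))
    msg <- c(msg, "rowData must have columns amplicon, pos, ref")
  if ("pos" %in% colnames(rd) && any(rd$pos < 1L))
    msg <- c(msg, "positions must be 1-based")
  if (all(need %in% SummarizedExperiment::assayNames(object))) {
    tot <- SummarizedExperiment::assay(object, "A") +
      SummarizedExperiment::assay(object, "C") +
      SummarizedExperiment::assay(object, "G") +
      SummarizedExperiment::assay(object, "T")
    if (any(tot != SummarizedExperiment::assay(object, "depth")))
      msg <- c(msg, "depth must equal the sum of the four base counts")
  }
  if (length(msg)) msg else TRUE
})

#' Gene model for effect annotation
#'
#' Exon structure and coding region of the gene carried by one amplicon, in
#' 1-based amplicon coordinates, together with the amplicon reference
#' sequence. The CDS may begin and end mid-amplicon; its exonic length must
#' be a multiple of three within the modelled region.
#'
#' @slot amplicon amplicon identifier.
#' @slot seq reference sequence of the amplicon (uppercase).
#' @slot strand \code{"+"} if the coding strand is the amplicon strand,
#'   \code{"-"} otherwise.
#' @slot exons two-column data.frame (\code{start}, \code{end}), 1-based
#'   inclusive, sorted, non-overlapping.
#' @slot cdsStart,cdsEnd first and last amplicon coordinate of the coding
#'   region (always \code{cdsStart <= cdsEnd}, independent of strand).
#'
#' @seealso [geneModel()], [annotateEffect()]
#' @export
setClass("GeneModel",
  representation(
    amplicon = "character",
    seq      = "character",
    strand   = "character",
    exons    = "data.frame",
    cdsStart = "integer",
    cdsEnd   = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (!all(c("start", "end") %in% colnames(ex)))
    msg <- c(msg, "exons must have columns start, end")
  else {
    if (any(ex$end < ex$start)) msg <- c(msg, "exon end < start")
    if (nrow(ex) > 1L) {
      if (is.unsorted(ex$start)) msg <- c(msg, "exons must be sorted")
      if (any(ex$start[-1L] <= ex$end[-nrow(ex)]))
        msg <- c(msg, "exons must not overlap")
    }
    if (any(ex$start < 1L) || any(ex$end > nchar(object@seq)))
      msg <- c(msg, "exons outside amplicon sequence")
  }
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (object@cdsStart > object@cdsEnd) msg <- c(msg, "cdsStart > cdsEnd")
  if (!length(msg)) {
    cdsLen <- sum(pmax(0L, pmin(ex$end, object@cdsEnd) -
                         pmax(ex$start, object@cdsStart) + 1L))
    if (cdsLen %% 3L != 0L)
      msg <- c(msg, "exonic CDS length must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoolingDesign", function(object) {
  sizes <- lengths(object@membership)
  cat("PoolingDesign '", object@schemeId, "': ", object@nPlates,
      " plates, ", length(object@poolIds), " pools (",
      paste(sprintf("%d %s", table(object@dimension)[unique(object@dimension)],
                    unique(object@dimension)), collapse = ", "),
      "), ", length(unique(unlist(object@membership))), " lines, ",
      min(sizes), "-", max(sizes), " lines/pool\n", sep = "")
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel '", object@amplicon, "' (", nchar(object@seq), " bp, strand ",
      object@strand, "): ", nrow(object@exons), " exon(s), CDS ",
      object@cdsStart, "-", object@cdsEnd, "\n", sep = "")
})
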