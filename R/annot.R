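## PARSESNP-style effect prediction: splice / nonsense / missense / silent /
## noncoding classification of point mutations against a gene model.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a gene model
#'
#' @param amplicon amplicon identifier.
#' @param seq amplicon reference sequence (character or \code{DNAString}).
#' @param exons data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive amplicon coordinates), sorted and non-overlapping.
#' @param cdsStart,cdsEnd amplicon coordinates bounding the coding region
#'   (\code{cdsStart <= cdsEnd} regardless of strand).
#' @param strand \code{"+"} if the coding strand is the amplicon strand.
#' @return a \linkS4class{GeneModel}.
#' @examples
#' m <- geneModel("amp1", "ATGGGATAAACT", data.frame(start = 1, end = 12),
#'                cdsStart = 1, cdsEnd = 9)
#' annotateEffect(m, 5, "G", "A")   # GGA -> GAA, missense
#' @export
geneModel <- function(amplicon, seq, exons, cdsStart, cdsEnd, strand = "+") {
  seq <- toupper(as.character(seq))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  new("GeneModel", amplicon = as.character(amplicon), seq = seq,
      strand = strand, exons = exons, cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd))
}

## exonic coordinates (amplicon frame) of the CDS, 5'->3' on the coding
## strand, plus the coding-strand base at each
.codingFrame <- function(model) {
  ex <- model@exons
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq.int(ex$start[i], ex$end[i])), use.names = FALSE)
  pos <- pos[pos >= model@cdsStart & pos <= model@cdsEnd]
  base <- strsplit(model@seq, "")[[1L]][pos]
  if (model@strand == "-") {
    pos <- rev(pos)
    base <- unname(.COMPLEMENT[rev(base)])
  }
  list(pos = pos, base = base)
}

.annotateOne <- function(model, pos, ref, alt, frame) {
  seqBase <- substr(model@seq, pos, pos)
  if (pos < 1L || pos > nchar(model@seq))
    stop("position ", pos, " outside amplicon '", model@amplicon, "'")
  if (seqBase != ref)
    stop("reference mismatch at ", model@amplicon, ":", pos,
         ": model has ", seqBase, ", record has ", ref,
         " (coordinate error?)")
  ex <- model@exons
  ## splice: first/last 2 bases of an intron (canonical GT..AG signals)
  if (nrow(ex) > 1L) {
    iStart <- ex$end[-nrow(ex)] + 1L
    iEnd <- ex$start[-1L] - 1L
    keep <- iEnd >= iStart
    if (any((pos >= iStart[keep] & pos <= iStart[keep] + 1L) |
            (pos >= iEnd[keep] - 1L & pos <= iEnd[keep])))
      return("splice")
  }
  inExon <- any(pos >= ex$start & pos <= ex$end)
  if (!inExon || pos < model@cdsStart || pos > model@cdsEnd)
    return("noncoding")
  cpos <- match(pos, frame$pos)
  if (is.na(cpos)) return("noncoding")
  codonIdx <- (cpos - 1L) %/% 3L
  offset <- (cpos - 1L) %% 3L
  codon <- frame$base[codonIdx * 3L + 1:3]
  if (anyNA(codon)) return("noncoding")   # truncated trailing codon
  newBase <- if (model@strand == "-") unname(.COMPLEMENT[alt]) else alt
  newCodon <- codon
  newCodon[offset + 1L] <- newBase
  code <- Biostrings::GENETIC_CODE
  oldAA <- unname(code[paste(codon, collapse = "")])
  newAA <- unname(code[paste(newCodon, collapse = "")])
  if (newAA == "*" && oldAA != "*") return("nonsense")
  if (newAA == oldAA) return("silent")
  "missense"
}

#' Predict the effect of a point mutation
#'
#' Classifies each mutation against the gene model: \code{"splice"} if it
#' hits the first or last 2 bases of an intron (the canonical GT donor / AG
#' acceptor window), \code{"nonsense"} if the altered codon becomes a stop,
#' \code{"missense"} if the encoded amino acid changes, \code{"silent"} if
#' synonymous, \code{"noncoding"} otherwise (introns beyond the splice
#' window, UTRs, flanks). Standard nuclear genetic code. A mismatch between
#' the record's reference base and the model sequence is an error (it
#' signals a coordinate problem).
#'
#' @param model a \linkS4class{GeneModel}.
#' @param pos,ref,alt mutation position(s) and bases (vectorised).
#' @return character vector of effect classes.
#' @export
annotateEffect <- function(model, pos, ref, alt) {
  frame <- .codingFrame(model)
  vapply(seq_along(pos), function(i)
    .annotateOne(model, as.integer(pos[i]), toupper(ref[i]),
                 toupper(alt[i]), frame), "")
}

#' Summarize effect classes
#'
#' Aggregates annotated mutation records into the three standard reporting
#' groups — \code{nonsense} (premature stop or splice junction),
#' \code{missense}, and \code{silent} (synonymous or non-coding) — with
#' percentages to one decimal.
#'
#' @param effects character vector of effect classes (\code{nonsense},
#'   \code{splice}, \code{missense}, \code{silent}, \code{noncoding}), or a
#'   data.frame with an \code{effect} column.
#' @param counts optional named vector of pre-tabulated group counts
#'   (\code{nonsense}, \code{missense}, \code{silent}), used instead of
#'   \code{effects}.
#' @return data.frame with columns \code{group}, \code{count},
#'   \code{percent}.
#' @examples
#' summarizeEffects(counts = c(nonsense = 18, missense = 181, silent = 233))
#' @export
summarizeEffects <- function(effects = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.data.frame(effects)) effects <- effects$effect
    if (length(effects) == 0L) stop("no annotated records")
    bad <- setdiff(unique(effects),
                   c("nonsense", "splice", "missense", "silent", "noncoding"))
    if (length(bad)) stop("unknown effect class: ", paste(bad, collapse = ","))
    counts <- c(
      nonsense = sum(effects %in% c("nonsense", "splice")),
      missense = sum(effects == "missense"),
      silent = sum(effects %in% c("silent", "noncoding")))
  } else {
    counts <- counts[c("nonsense", "missense", "silent")]
  }
  total <- sum(counts)
  if (total == 0L) stop("no annotated records")
  data.frame(group = names(counts), count = as.integer(counts),
             percent = round(100 * as.integer(counts) / total, 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a gene model
#'
#' \code{readGeneModelTsv} reads a simple feature TSV (columns
#' \code{amplicon, feature, start, end, strand}; features \code{exon} and
#' \code{CDS}); \code{readGeneModelGff} reads the exon/CDS features of a
#' GFF3 file via \pkg{rtracklayer}. In both cases the CDS bounds are the
#' extremes of the CDS features and the strand is taken from them.
#'
#' @param path feature file path.
#' @param amplicon amplicon (seqname) to extract.
#' @param seq amplicon reference sequence.
#' @return a \linkS4class{GeneModel}.
#' @export
readGeneModelTsv <- function(path, amplicon, seq) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab <- tab[tab$amplicon == amplicon, , drop = FALSE]
  if (!nrow(tab)) stop("no features for amplicon '", amplicon, "'")
  ex <- tab[tab$feature == "exon", c("start", "end")]
  cds <- tab[tab$feature == "CDS", , drop = FALSE]
  if (!nrow(ex) || !nrow(cds)) stop("model needs exon and CDS features")
  geneModel(amplicon, seq, ex, min(cds$start), max(cds$end),
            strand = cds$strand[1L])
}

#' @rdname readGeneModelTsv
#' @export
readGeneModelGff <- function(path, amplicon, seq) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3 gene models")
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == amplicon]
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (!length(ex) || !length(cds)) stop("model needs exon and CDS features")
  geneModel(amplicon, seq,
            data.frame(start = GenomicRanges::start(ex),
                       end = GenomicRanges::end(ex)),
            min(GenomicRanges::start(cds)), max(GenomicRanges::end(cds)),
            strand = as.character(GenomicRanges::strand(cds))[1L])
}
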