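## SAMtools mpileup text -> quality-filtered base counts -> substitution
## frequencies.

## Strip read-start (^ + mapping-quality char), read-end ($) and indel
## sub-sequences (+N/-N followed by N inserted/deleted bases) from an
## mpileup base string, leaving one symbol per base-quality character.
.stripPileupMarkup <- function(bases) {
  bases <- gsub("\\^.", "", bases)
  bases <- gsub("\\$", "", bases, fixed = FALSE)
  repeat {
    m <- regexpr("[+-][0-9]+", bases)
    if (m == -1L) break
    len <- attr(m, "match.length")
    n <- as.integer(substr(bases, m + 1L, m + len - 1L))
    bases <- paste0(substr(bases, 1L, m - 1L),
                    substr(bases, m + len + n, nchar(bases)))
  }
  bases
}

#' Base counts from an mpileup stream
#'
#' Parses SAMtools mpileup text (one pool) into per-position A/C/G/T counts,
#' keeping only bases whose Phred quality strictly exceeds
#' \code{minBaseQuality}. \code{.}/\code{,} are counted as the reference
#' base; strand is collapsed (upper/lower case merged); read start/end
#' markers and indel sub-sequences are consumed per the mpileup grammar
#' without contributing; deletions (\code{*}), reference skips and \code{N}
#' contribute neither to the counts nor to the filtered depth.
#'
#' @param input path to an mpileup text file, or a character vector of
#'   mpileup lines.
#' @param minBaseQuality Phred threshold; bases with quality
#'   \code{<= minBaseQuality} are discarded (default 20).
#' @param qualityOffset ASCII offset of the quality encoding (33 =
#'   Phred+33, Illumina 1.8+).
#' @return data.frame with columns \code{amplicon, pos, ref, nA, nC, nG,
#'   nT, depth} (\code{depth} is the filtered depth, i.e. the sum of the
#'   four counts).
#' @examples
#' countsFromPileup("amp1\t475\tC\t10\t..TT......\tIIIIIIIIII")
#' @export
countsFromPileup <- function(input, minBaseQuality = 20L,
                             qualityOffset = 33L) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- data.frame(amplicon = character(n), pos = integer(n),
                    ref = character(n), nA = integer(n), nC = integer(n),
                    nG = integer(n), nT = integer(n), depth = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L)
      stop("malformed pileup line ", i, ": expected >= 6 fields, got ",
           length(f))
    pos <- suppressWarnings(as.integer(f[2L]))
    rawDepth <- suppressWarnings(as.integer(f[4L]))
    if (is.na(pos) || is.na(rawDepth))
      stop("malformed pileup line ", i, ": non-numeric pos or depth")
    ref <- toupper(f[3L])
    cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    if (rawDepth > 0L) {
      sym <- .stripPileupMarkup(f[5L])
      quals <- f[6L]
      if (nchar(sym) != nchar(quals))
        stop("pileup line ", i, ": base string (", nchar(sym),
             " symbols after markup) does not match quality string (",
             nchar(quals), ")")
      chars <- strsplit(sym, "")[[1L]]
      q <- utf8ToInt(quals) - qualityOffset
      keep <- q > minBaseQuality
      chars <- toupper(chars)
      chars[chars %in% c(".", ",")] <- ref
      counted <- keep & chars %in% .BASES
      if (any(counted)) {
        tb <- table(chars[counted])
        cnt[names(tb)] <- as.integer(tb)
      }
    }
    out$amplicon[i] <- f[1L]
    out$pos[i] <- pos
    out$ref[i] <- ref
    out$nA[i] <- cnt[["A"]]
    out$nC[i] <- cnt[["C"]]
    out$nG[i] <- cnt[["G"]]
    out$nT[i] <- cnt[["T"]]
    out$depth[i] <- sum(cnt)
  }
  out
}

#' Read a count TSV
#'
#' Reads the tab-separated count dialect written by [writeFixture()] /
#' emitted by \code{countsFromPileup} (columns \code{amplicon, pos, ref,
#' nA, nC, nG, nT, depth}).
#'
#' @param path TSV file path.
#' @return count data.frame.
#' @export
readCountsTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "character",
                                          "integer", "integer", "integer",
                                          "integer", "integer"))
  need <- c("amplicon", "pos", "ref", "nA", "nC", "nG", "nT", "depth")
  if (!all(need %in% colnames(tab)))
    stop("count TSV must have columns ", paste(need, collapse = ", "))
  tab
}

#' Assemble per-pool tables into a PoolCounts object
#'
#' @param tables named list (names = pool ids) of count data.frames, all
#'   covering the same positions in the same order.
#' @param dimension optional per-pool dimension labels (or a
#'   \linkS4class{PoolingDesign} from which they are taken).
#' @return a \linkS4class{PoolCounts}.
#' @export
assemblePoolCounts <- function(tables, dimension = NULL) {
  ids <- names(tables)
  if (is.null(ids)) stop("tables must be named by pool id")
  first <- tables[[1L]]
  for (t in tables)
    if (!identical(t[c("amplicon", "pos", "ref")],
                   first[c("amplicon", "pos", "ref")]))
      stop("pool tables cover different positions")
  grab <- function(col) {
    m <- vapply(tables, function(t) as.integer(t[[col]]),
                integer(nrow(first)))
    colnames(m) <- ids
    m
  }
  counts <- list(A = grab("nA"), C = grab("nC"), G = grab("nG"),
                 T = grab("nT"))
  if (is(dimension, "PoolingDesign"))
    dimension <- unname(dimension@dimension[ids])
  poolCounts(counts, first[c("amplicon", "pos", "ref")],
             poolIds = as.integer(ids), dimension = dimension)
}

#' Substitution frequencies
#'
#' For every pool, position and substitution ref>alt, the frequency
#' \code{alt count / filtered depth}. Zero-depth positions are flagged
#' \code{noData} rather than divided.
#'
#' @param counts a \linkS4class{PoolCounts}, or a single-pool count
#'   data.frame (then \code{pool} labels the output).
#' @param pool pool label used when \code{counts} is a data.frame.
#' @return data.frame with columns \code{pool, amplicon, pos, ref, alt,
#'   count, depth, freq, noData}; three rows (the non-reference bases) per
#'   pool position.
#' @export
baseFrequencies <- function(counts, pool = NA) {
  if (is(counts, "PoolCounts")) {
    res <- lapply(colnames(counts), function(id)
      baseFrequencies(poolTable(counts, id), pool = id))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    return(out)
  }
  tab <- counts
  n <- nrow(tab)
  cmat <- cbind(A = tab$nA, C = tab$nC, G = tab$nG, T = tab$nT)
  altTable <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
  idx <- rep(seq_len(n), each = 3L)
  alt <- unlist(altTable[tab$ref], use.names = FALSE)
  count <- cmat[cbind(idx, match(alt, .BASES))]
  depth <- tab$depth[idx]
  data.frame(pool = pool, amplicon = tab$amplicon[idx], pos = tab$pos[idx],
             ref = tab$ref[idx], alt = alt, count = count, depth = depth,
             freq = ifelse(depth > 0L, count / depth, NA_real_),
             noData = depth == 0L, stringsAsFactors = FALSE)
}
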