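## Tri-dimensional pooling: build, encode, decode, validate.

.PLATE_ROWS <- LETTERS[1:8]
.PLATE_COLS <- 1:12

#' Line addresses
#'
#' A line address identifies one M2 line by its plate (DNA box), row letter
#' and column number, encoded as \code{"P<plate>:<row><column>"} (e.g.
#' \code{"P4:E5"} = plate 4, well E5). Addresses are plain character strings
#' so pool memberships stay light; \code{parseAddress()} recovers the
#' components.
#'
#' @param plate 1-based plate index (vectorised).
#' @param row row letter \code{"A"}..\code{"H"} (vectorised).
#' @param column column number 1..12 (vectorised).
#' @return \code{lineAddress}: character vector of address keys.
#'   \code{parseAddress}: data.frame with columns \code{plate}, \code{row},
#'   \code{column}, \code{well}.
#' @examples
#' lineAddress(4, "E", 5)
#' parseAddress(c("P1:A1", "P4:E5"))
#' @export
lineAddress <- function(plate, row, column) {
  plate <- as.integer(plate)
  column <- as.integer(column)
  stopifnot(all(plate >= 1L), all(row %in% .PLATE_ROWS),
            all(column %in% .PLATE_COLS))
  sprintf("P%d:%s%d", plate, row, column)
}

#' @rdname lineAddress
#' @param address character vector of address keys.
#' @export
parseAddress <- function(address) {
  m <- regmatches(address, regexec("^P([0-9]+):([A-H])([0-9]{1,2})$", address))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed line address: ", paste(address[bad], collapse = ", "))
  data.frame(
    plate = as.integer(vapply(m, `[`, "", 2L)),
    row = vapply(m, `[`, "", 3L),
    column = as.integer(vapply(m, `[`, "", 4L)),
    well = paste0(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 4L))
  )
}

## ---- scheme registry ----------------------------------------------------

.schemes <- new.env(parent = emptyenv())

.canonical384 <- function(nPlates) {
  if (nPlates != 4L)
    stop("scheme 'canonical384' requires 4 plates, got ", nPlates)
  plates <- seq_len(nPlates)
  grid <- expand.grid(column = .PLATE_COLS, row = .PLATE_ROWS, plate = plates,
                      stringsAsFactors = FALSE)
  addr <- lineAddress(grid$plate, grid$row, grid$column)
  membership <- vector("list", 12L)
  dimension <- character(12L)
  for (k in 1:4) {                      # pools 1-4: column blocks of 3
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    membership[[k]] <- addr[grid$column %in% cols]
    dimension[k] <- "column"
  }
  for (k in 1:4) {                      # pools 5-8: row pairs
    rows <- .PLATE_ROWS[(2L * (k - 1L) + 1L):(2L * k)]
    membership[[4L + k]] <- addr[grid$row %in% rows]
    dimension[4L + k] <- "row"
  }
  for (k in 1:4) {                      # pools 9-12: whole plates
    membership[[8L + k]] <- addr[grid$plate == k]
    dimension[8L + k] <- "plate"
  }
  list(poolIds = 1:12, dimension = dimension, membership = membership)
}

#' Pooling-scheme registry
#'
#' Layouts are data, not code: a scheme maps pool ids to explicit well lists
#' (or is generated by a built-in constructor). \code{"canonical384"} is
#' registered at load time: four plates of 96 lines pooled into 12 pools of
#' 96 — pools 1–4 are column blocks \{1–3\},\{4–6\},\{7–9\},\{10–12\} across
#' all plates, pools 5–8 are row pairs \{A,B\},\{C,D\},\{E,F\},\{G,H\} across
#' all plates, and pools 9–12 are plates 1–4. Variant layouts (e.g. designs
#' that rotate the column/row pattern per plate) can be registered from a
#' JSON file without code changes.
#'
#' @param schemeId scheme identifier.
#' @param pools named list: pool id -> list with elements \code{dimension}
#'   and \code{wells} (character vector of line addresses).
#' @param nPlates number of plates the scheme covers.
#' @return \code{registerScheme}: the scheme id, invisibly.
#'   \code{registeredSchemes}: character vector of known scheme ids.
#' @export
registerScheme <- function(schemeId, pools, nPlates) {
  poolIds <- as.integer(names(pools))
  if (anyNA(poolIds)) stop("pool ids must be integers")
  def <- list(
    poolIds = poolIds,
    dimension = vapply(pools, function(p) p$dimension, ""),
    membership = lapply(pools, function(p) as.character(p$wells)),
    nPlates = as.integer(nPlates)
  )
  assign(schemeId, def, envir = .schemes)
  invisible(schemeId)
}

#' @rdname registerScheme
#' @export
registeredSchemes <- function() sort(unique(c("canonical384", ls(.schemes))))

#' @rdname registerScheme
#' @param path JSON file mapping scheme id -> \{n_plates, pools: \{id:
#'   \{dimension, wells\}\}\}.
#' @export
loadSchemes <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (id in names(cfg)) {
    sc <- cfg[[id]]
    pools <- lapply(sc$pools, function(p)
      list(dimension = p$dimension, wells = unlist(p$wells)))
    registerScheme(id, pools, sc$n_plates)
  }
  invisible(names(cfg))
}

#' Build a pooling design
#'
#' Instantiates a registered pooling layout for a population of
#' \code{nPlates} 96-well plates. The default \code{"canonical384"} scheme
#' pools 384 lines into 12 pools of 96 (see [registerScheme()]); a full pool
#' triple then resolves a mutation to 6 lines (2 rows x 3 columns on one
#' plate).
#'
#' @param nPlates number of plates (the canonical scheme requires 4).
#' @param schemeId registered scheme identifier.
#' @return a \linkS4class{PoolingDesign}.
#' @examples
#' d <- buildDesign(4, "canonical384")
#' d
#' @export
buildDesign <- function(nPlates = 4L, schemeId = "canonical384") {
  nPlates <- as.integer(nPlates)
  if (nPlates < 1L) stop("nPlates must be >= 1")
  if (schemeId == "canonical384") {
    def <- .canonical384(nPlates)
  } else if (exists(schemeId, envir = .schemes)) {
    def <- get(schemeId, envir = .schemes)
    if (!is.null(def$nPlates) && def$nPlates != nPlates)
      stop("scheme '", schemeId, "' requires ", def$nPlates,
           " plates, got ", nPlates)
  } else {
    stop("unknown pooling scheme: '", schemeId, "'")
  }
  names(def$membership) <- as.character(def$poolIds)
  names(def$dimension) <- as.character(def$poolIds)
  new("PoolingDesign", schemeId = schemeId, nPlates = nPlates,
      poolIds = def$poolIds, dimension = def$dimension,
      membership = def$membership)
}

#' Pools carrying a line
#'
#' Returns the pool triple (one pool per dimension) whose libraries contain
#' DNA from the given line.
#'
#' @param design a \linkS4class{PoolingDesign}.
#' @param address a line address key (see [lineAddress()]), or the plate as
#'   an integer combined with \code{row}/\code{column}.
#' @param row,column optional well coordinates when \code{address} is a
#'   plate number.
#' @return sorted integer vector of pool ids, one per dimension.
#' @examples
#' d <- buildDesign()
#' poolsForLine(d, 4, "E", 5)   # {2, 7, 12}
#' @export
poolsForLine <- function(design, address, row = NULL, column = NULL) {
  if (!is.null(row)) address <- lineAddress(address, row, column)
  hit <- vapply(design@membership, function(m) address %in% m, NA)
  if (!any(hit))
    stop("address ", address, " is outside the design")
  sort(design@poolIds[hit])
}

#' Decode a pool set to candidate lines
#'
#' Intersects the memberships of the given pools. A full triple (one pool
#' per dimension) under the canonical 384-line scheme resolves to exactly 6
#' lines; fewer pools give the correspondingly larger intersection, so
#' partial evidence can still be reported.
#'
#' @param design a \linkS4class{PoolingDesign}.
#' @param pools integer vector of pool ids, at most one per dimension.
#' @return character vector of line addresses, in plate/row/column order.
#' @examples
#' d <- buildDesign()
#' decodePools(d, c(2, 7, 12))   # plate 4, wells E4..F6
#' @export
decodePools <- function(design, pools) {
  pools <- as.integer(pools)
  if (length(pools) == 0L) stop("empty pool set")
  unknown <- setdiff(pools, design@poolIds)
  if (length(unknown))
    stop("unknown pool id(s): ", paste(unknown, collapse = ", "))
  dims <- design@dimension[as.character(pools)]
  if (anyDuplicated(dims))
    stop("inconsistent pool signature: two pools from dimension '",
         dims[duplicated(dims)][1L], "'")
  sets <- design@membership[as.character(pools)]
  hit <- Reduce(intersect, sets)
  if (length(hit) == 0L) stop("pools have an empty intersection")
  p <- parseAddress(hit)
  hit[order(p$plate, p$row, p$column)]
}

#' Validate a pooling design
#'
#' Checks the combinatorial guarantees the caller relies on: every line in
#' exactly one pool per dimension, the expected pool size, pools within a
#' dimension partitioning the population, and every full triple decoding to
#' the expected number of lines (brute-force enumeration over all triples).
#'
#' @param design a \linkS4class{PoolingDesign}.
#' @param poolSize expected lines per pool (96 for the canonical scheme).
#' @param tripleSize expected lines resolved by a full triple (6).
#' @return list with \code{valid} (logical), \code{violations} (character),
#'   \code{tripleSizes} (named integer vector over all full triples) and
#'   \code{nLines}.
#' @examples
#' rep <- validateDesign(buildDesign())
#' rep$valid
#' @export
validateDesign <- function(design, poolSize = 96L, tripleSize = 6L) {
  v <- character()
  allLines <- sort(unique(unlist(design@membership)))
  sizes <- lengths(design@membership)
  bad <- sizes != poolSize
  if (any(bad))
    v <- c(v, sprintf("pool %s has %d lines (expected %d)",
                      names(sizes)[bad], sizes[bad], poolSize))
  ## one pool per dimension per line
  for (dim in unique(design@dimension)) {
    ids <- as.character(design@poolIds[design@dimension == dim])
    mem <- unlist(design@membership[ids])
    if (anyDuplicated(mem))
      v <- c(v, sprintf("dimension '%s': line(s) in >1 pool: %s", dim,
                        paste(unique(mem[duplicated(mem)]), collapse = ",")))
    missing <- setdiff(allLines, mem)
    if (length(missing))
      v <- c(v, sprintf("dimension '%s': %d line(s) in no pool", dim,
                        length(missing)))
  }
  ## brute-force all full triples
  byDim <- split(design@poolIds, design@dimension[as.character(design@poolIds)])
  triples <- expand.grid(byDim, stringsAsFactors = FALSE)
  tsz <- integer(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    ids <- as.character(unlist(triples[i, ]))
    tsz[i] <- length(Reduce(intersect, design@membership[ids]))
  }
  names(tsz) <- apply(triples, 1L, function(r)
    paste(sort(as.integer(r)), collapse = "+"))
  bad <- tsz != tripleSize
  if (any(bad))
    v <- c(v, sprintf("triple {%s} decodes to %d lines (expected %d)",
                      names(tsz)[bad], tsz[bad], tripleSize))
  list(valid = length(v) == 0L, violations = v, tripleSizes = tsz,
       nLines = length(allLines))
}

## ---- design JSON --------------------------------------------------------

#' Read or write a design as JSON
#'
#' The on-disk form is the scheme-registry format (see [loadSchemes()]):
#' scheme id, plate count, and explicit well lists per pool, so a design
#' file is self-contained and layout variants travel with the data.
#'
#' @param design a \linkS4class{PoolingDesign}.
#' @param path output (input) file path.
#' @return \code{writeDesignJson}: \code{path}, invisibly.
#'   \code{readDesignJson}: a \linkS4class{PoolingDesign}.
#' @export
writeDesignJson <- function(design, path) {
  pools <- lapply(as.character(design@poolIds), function(id)
    list(dimension = unname(design@dimension[id]),
         wells = design@membership[[id]]))
  names(pools) <- as.character(design@poolIds)
  obj <- list()
  obj[[design@schemeId]] <- list(n_plates = design@nPlates, pools = pools)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname writeDesignJson
#' @export
readDesignJson <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(cfg) != 1L) stop("design file must contain exactly one scheme")
  id <- names(cfg)[1L]
  sc <- cfg[[1L]]
  pools <- lapply(sc$pools, function(p)
    list(dimension = p$dimension, wells = unlist(p$wells)))
  registerScheme(id, pools, sc$n_plates)
  buildDesign(sc$n_plates, id)
}
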