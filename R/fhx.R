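#' Read an FHX2-style fire-scar chronology file
#'
#' FHX2 is the community interchange format for fire-scar chronologies: a
#' header declaring the first calendar year, the number of series (trees) and
#' the series-id length, an id block in which the ids are written vertically,
#' and then one fixed-width row per calendar year with one code character per
#' series.
#'
#' The dialect supported here is the minimal code set needed for spreading-
#' fire analysis:
#' \describe{
#'   \item{uppercase letter}{fire scar in that year; `D` marks a dormant-season
#'     scar, every other letter (`U`, `E`, `M`, `L`, `A`, ...) is retained as
#'     season `unknown`.}
#'   \item{`|`}{recorder year (open scar face, able to record fire).}
#'   \item{`.`}{non-recorder year within the series span.}
#'   \item{`-` or space}{null (outside the series span).}
#' }
#'
#' @param path path to the FHX file.
#' @return an object of class `fhx`: a list with `first_year`, the year-by-
#'   series character `codes` matrix (rownames = years, colnames = tree ids),
#'   and `tree_ids`.  Use [fhx_scars()] and [fhx_series()] to extract the
#'   scar records and per-series recorder spans.
#' @seealso [write_fhx()], [as_fhx()]
#' @export
read_fhx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("FHX parse error at line 1: file too short in ", path)
  if (!grepl("^(FHX2|FIRE2) FORMAT", trimws(lines[1L])))
    stop("FHX parse error at line 1: expected 'FHX2 FORMAT', got '", lines[1L], "'")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]]))
  if (length(hdr) != 3L || anyNA(hdr))
    stop("FHX parse error at line 2: expected '<first year> <n series> <id length>'")
  first_year <- hdr[1L]; n_series <- hdr[2L]; id_len <- hdr[3L]
  if (n_series < 1L || id_len < 1L)
    stop("FHX parse error at line 2: series count and id length must be positive")
  if (length(lines) < 2L + id_len)
    stop("FHX parse error: id block truncated (need ", id_len, " lines)")

  pad <- function(s, n) formatC(s, width = -n)  # right-pad with spaces
  id_block <- vapply(lines[3:(2L + id_len)], pad, character(1L), n = n_series)
  id_chars <- do.call(rbind, strsplit(id_block, ""))
  tree_ids <- trimws(apply(id_chars, 2L, paste, collapse = ""))
  empty <- tree_ids == ""
  tree_ids[empty] <- paste0("series", which(empty))
  if (anyDuplicated(tree_ids))
    stop("FHX parse error: duplicate series ids: ",
         paste(unique(tree_ids[duplicated(tree_ids)]), collapse = ", "))

  body <- lines[-(1:(2L + id_len))]
  body <- body[trimws(body) != ""]
  if (length(body) == 0L) stop("FHX parse error: no data rows")
  codes <- matrix("-", nrow = length(body), ncol = n_series,
                  dimnames = list(first_year + seq_along(body) - 1L, tree_ids))
  for (i in seq_along(body)) {
    row <- strsplit(body[i], "")[[1L]]
    if (length(row) > n_series && any(row[-(1:n_series)] != " "))
      stop("FHX parse error: data row for year ", first_year + i - 1L,
           " has more columns than the ", n_series, " declared series")
    if (length(row) < n_series) {
      miss <- tree_ids[(length(row) + 1L):n_series]
      stop("series length mismatch: year ", first_year + i - 1L,
           " row missing code for series ", miss[1L])
    }
    codes[i, ] <- row[1:n_series]
  }
  codes[codes == " "] <- "-"
  structure(list(first_year = first_year, codes = codes, tree_ids = tree_ids),
            class = "fhx")
}

#' @export
print.fhx <- function(x, ...) {
  yrs <- as.integer(rownames(x$codes))
  cat(sprintf("<fhx> %d series, years %d-%d, %d scar codes\n",
              length(x$tree_ids), min(yrs), max(yrs),
              sum(grepl("[A-Z]", x$codes))))
  invisible(x)
}

#' Extract fire-scar records from an fhx object
#'
#' @param x an `fhx` object.
#' @param site_id site id to stamp on the records.
#' @return data frame with columns `site_id`, `tree_id`, `scar_year_start`,
#'   `scar_year_end`, `season` (`dormant` for `D` codes, otherwise `unknown`).
#'   Single-year codes always have `scar_year_end == scar_year_start`.
#' @export
fhx_scars <- function(x, site_id = "site") {
  stopifnot(inherits(x, "fhx"))
  is_scar <- grepl("[A-Z]", x$codes)
  dim(is_scar) <- dim(x$codes)
  hit <- which(is_scar, arr.ind = TRUE)
  yrs <- as.integer(rownames(x$codes))
  season <- ifelse(x$codes[hit] == "D", "dormant", "unknown")
  out <- data.frame(
    site_id = rep(site_id, nrow(hit)),
    tree_id = x$tree_ids[hit[, 2L]],
    scar_year_start = yrs[hit[, 1L]],
    scar_year_end = yrs[hit[, 1L]],
    season = season,
    stringsAsFactors = FALSE
  )
  out[order(out$tree_id, out$scar_year_start), , drop = FALSE]
}

#' Per-series recorder spans
#'
#' A tree is treated as a recorder from its first scar (or explicit recorder
#' code) through its last non-null year.
#'
#' @param x an `fhx` object.
#' @return data frame: `tree_id`, `first_year`, `last_year`,
#'   `first_scar_year` (NA if never scarred).
#' @export
fhx_series <- function(x) {
  stopifnot(inherits(x, "fhx"))
  yrs <- as.integer(rownames(x$codes))
  out <- lapply(seq_along(x$tree_ids), function(j) {
    col <- x$codes[, j]
    live <- which(col != "-")
    scar <- which(grepl("[A-Z]", col))
    data.frame(tree_id = x$tree_ids[j],
               first_year = if (length(live)) yrs[min(live)] else NA_integer_,
               last_year = if (length(live)) yrs[max(live)] else NA_integer_,
               first_scar_year = if (length(scar)) yrs[min(scar)] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build an fhx object from scar records and a series table
#'
#' @param scars data frame with `tree_id`, `scar_year_start`, optional
#'   `season` (`dormant` writes a `D`, everything else a `U`).
#' @param series data frame with `tree_id`, `first_year`, `last_year` giving
#'   each series span.  Years between a tree's `first_year` and its first
#'   scar are written as non-recorder (`.`), from the first scar to
#'   `last_year` as recorder (`|`), and outside the span as null (`-`).
#' @param first_year,last_year optional explicit chronology span; defaults to
#'   the union of series spans.
#' @return an `fhx` object.
#' @export
as_fhx <- function(scars, series, first_year = NULL, last_year = NULL) {
  if (nrow(series) < 1L) stop("at least one series must be declared")
  if (is.null(first_year))
    first_year <- min(series$first_year, scars$scar_year_start, na.rm = TRUE)
  if (is.null(last_year))
    last_year <- max(series$last_year, scars$scar_year_start, na.rm = TRUE)
  if (!is.finite(first_year) || !is.finite(last_year))
    stop("chronology span undefined: give first_year/last_year explicitly")
  yrs <- seq.int(first_year, last_year)
  ids <- as.character(series$tree_id)
  codes <- matrix("-", nrow = length(yrs), ncol = length(ids),
                  dimnames = list(yrs, ids))
  for (j in seq_along(ids)) {
    fy <- series$first_year[j]; ly <- series$last_year[j]
    if (is.na(fy) || is.na(ly)) next
    sc <- scars[scars$tree_id == ids[j], , drop = FALSE]
    if (anyDuplicated(sc$scar_year_start)) {
      dup <- sc$scar_year_start[duplicated(sc$scar_year_start)]
      agree <- all(vapply(unique(dup), function(y) {
        length(unique(sc$season[sc$scar_year_start == y])) == 1L
      }, logical(1L)))
      if (!agree)
        stop("contradictory codes for tree ", ids[j], " (conflicting seasons ",
             "for one year)")
      sc <- sc[!duplicated(sc$scar_year_start), , drop = FALSE]
    }
    span <- yrs >= fy & yrs <= ly
    first_scar <- suppressWarnings(min(sc$scar_year_start))
    if (is.finite(first_scar)) {
      codes[span & yrs < first_scar, j] <- "."
      codes[span & yrs >= first_scar, j] <- "|"
    } else {
      codes[span, j] <- "."
    }
    if (nrow(sc)) {
      season <- if ("season" %in% names(sc)) sc$season else "unknown"
      codes[match(sc$scar_year_start, yrs), j] <-
        ifelse(season == "dormant", "D", "U")
    }
  }
  structure(list(first_year = as.integer(first_year), codes = codes,
                 tree_ids = ids),
            class = "fhx")
}

#' Write an fhx object to an FHX2 file
#'
#' `read_fhx(write_fhx(x, path))` reproduces `x`'s code matrix exactly.
#'
#' @param x an `fhx` object (see [as_fhx()]).
#' @param path output path.
#' @export
write_fhx <- function(x, path) {
  stopifnot(inherits(x, "fhx"))
  ids <- x$tree_ids
  id_len <- max(nchar(ids))
  id_chars <- vapply(ids, function(s) {
    padded <- formatC(s, width = -id_len)
    strsplit(padded, "")[[1L]]
  }, character(id_len))
  id_block <- apply(matrix(id_chars, nrow = id_len), 1L, paste, collapse = "")
  rows <- apply(x$codes, 1L, paste, collapse = "")
  writeLines(c("FHX2 FORMAT",
               paste(x$first_year, length(ids), id_len),
               id_block,
               "",
               rows), path)
  invisible(path)
}
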