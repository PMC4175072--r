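#' Lightweight single-band raster grid
#'
#' A `fire_grid` is a numeric (or integer) matrix with georeferencing
#' attributes: square cell size in meters and the coordinates of the
#' lower-left corner.  Row 1 is the northernmost row (the usual raster
#' convention), columns run west to east.  `NA` is the nodata value.
#'
#' All raster operations in the package (terrain derivation, rule mapping,
#' severity overlays) work on aligned `fire_grid` objects: same dimensions,
#' cell size and origin.
#'
#' @param values numeric matrix; row 1 = north.
#' @param cell_m cell size in meters (square cells).
#' @param xll,yll map coordinates of the lower-left corner of the grid.
#' @return object of class `fire_grid`.
#' @export
fire_grid <- function(values, cell_m = 30, xll = 0, yll = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_m) || length(cell_m) != 1L || cell_m <= 0)
    stop("`cell_m` must be a single positive number")
  structure(values, cell_m = as.numeric(cell_m),
            xll = as.numeric(xll), yll = as.numeric(yll),
            class = c("fire_grid", class(values)))
}

#' @export
print.fire_grid <- function(x, ...) {
  cat(sprintf("<fire_grid> %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "cell_m"), attr(x, "xll"), attr(x, "yll")))
  v <- as.vector(x)
  cat(sprintf("  values: %d cells, %d NA; range [%s, %s]\n",
              length(v), sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' @rdname fire_grid
#' @param x object to test.
#' @export
is_fire_grid <- function(x) inherits(x, "fire_grid")

#' Cell size (m) of a grid
#' @param x a `fire_grid`.
#' @export
cell_size <- function(x) attr(x, "cell_m")

#' Cell area in hectares
#' @param x a `fire_grid`.
#' @export
cell_area_ha <- function(x) attr(x, "cell_m")^2 / 1e4

#' Check that grids share shape and georeferencing
#'
#' @param ... two or more `fire_grid` objects.
#' @param tol tolerance on origin/cell-size comparison.
#' @return invisibly `TRUE`; stops with an informative error on misalignment.
#' @export
check_aligned <- function(..., tol = 1e-6) {
  gs <- list(...)
  if (length(gs) < 2L) return(invisible(TRUE))
  ref <- gs[[1L]]
  for (i in seq_along(gs)[-1L]) {
    g <- gs[[i]]
    if (!is_fire_grid(g)) stop("argument ", i, " is not a fire_grid")
    if (!identical(dim(g), dim(ref)))
      stop("misaligned grids: dimensions differ (", paste(dim(ref), collapse = "x"),
           " vs ", paste(dim(g), collapse = "x"), ")")
    if (abs(cell_size(g) - cell_size(ref)) > tol ||
        abs(attr(g, "xll") - attr(ref, "xll")) > tol ||
        abs(attr(g, "yll") - attr(ref, "yll")) > tol)
      stop("misaligned grids: cell size or origin differs")
  }
  invisible(TRUE)
}

#' Construct a grid with the same georeferencing as a template
#' @param template a `fire_grid` supplying shape and georeferencing.
#' @param values optional matrix/vector of replacement values.
#' @export
grid_like <- function(template, values = NA_real_) {
  m <- matrix(values, nrow = nrow(template), ncol = ncol(template))
  fire_grid(m, cell_m = cell_size(template),
            xll = attr(template, "xll"), yll = attr(template, "yll"))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster interchange (`.asc`): a 6-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of whitespace-separated values, north first.
#'
#' @param path file path.
#' @return `read_ascii_grid` returns a `fire_grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("not an ASCII grid: fewer than 7 lines in ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L) stop("malformed ASCII grid header at line ", i)
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing: ", paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  fire_grid(m, cell_m = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner)
}

#' @rdname read_ascii_grid
#' @param grid a `fire_grid` to write.
#' @param nodata numeric code used for `NA` cells on disk.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(is_fire_grid(grid))
  m <- unclass(grid)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    paste("xllcorner", attr(grid, "xll")),
    paste("yllcorner", attr(grid, "yll")),
    paste("cellsize", cell_size(grid)),
    paste("NODATA_value", nodata)
  ), con)
  apply(m, 1L, function(r) writeLines(paste(format(r, trim = TRUE, scientific = FALSE),
                                            collapse = " "), con))
  invisible(path)
}
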