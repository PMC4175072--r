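#' Read tree and site tables
#'
#' Delimited text (comma or tab, sniffed from the header line) with one header
#' row.  Required columns are checked by name; unknown columns are preserved.
#' Blank numeric fields become `NA` (missing is never silently coerced to 0).
#'
#' Tree tables require `site_id`, `tree_id`, `species`, `inner_ring_year`;
#' optional columns include `pith_offset_yr`, `coring_height_offset_yr`,
#' `status`, `dbh_cm`.  Site tables require `site_id`, `elevation_m`,
#' `slope_deg`, `aspect_deg`, `cover_type`; optional `site_type`, `area_ha`,
#' `dist_grassland_m`, `dist_ravine_m`, `x`, `y`.
#'
#' @param path path to a delimited text file.
#' @return a data frame of typed records.
#' @name read_tables
NULL

sniff_delim <- function(path) {
  hdr <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", hdr)) "\t" else ","
}

read_delim_table <- function(path, required, year_cols = character(),
                             numeric_cols = character()) {
  sep <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         " in ", path)
  for (col in intersect(c(year_cols, numeric_cols), names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      kind <- if (col %in% year_cols) "unparseable year" else "unparseable number"
      stop(kind, " in column '", col, "' at row ", bad[1L], ": '", raw[bad[1L]], "'")
    }
    df[[col]] <- if (col %in% year_cols) as.integer(val) else val
  }
  df
}

#' @rdname read_tables
#' @export
read_tree_table <- function(path) {
  df <- read_delim_table(
    path,
    required = c("site_id", "tree_id", "species", "inner_ring_year"),
    year_cols = c("inner_ring_year", "establishment_year"),
    numeric_cols = c("pith_offset_yr", "coring_height_offset_yr", "dbh_cm")
  )
  for (col in c("pith_offset_yr", "coring_height_offset_yr"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  if (!"status" %in% names(df)) df$status <- "live"
  df
}

#' @rdname read_tables
#' @export
read_site_table <- function(path) {
  df <- read_delim_table(
    path,
    required = c("site_id", "elevation_m", "slope_deg", "aspect_deg", "cover_type"),
    numeric_cols = c("elevation_m", "slope_deg", "aspect_deg", "area_ha",
                     "dist_grassland_m", "dist_ravine_m", "x", "y")
  )
  bad_slope <- which(!is.na(df$slope_deg) & (df$slope_deg < 0 | df$slope_deg > 90))
  if (length(bad_slope))
    stop("slope_deg outside [0, 90] at row ", bad_slope[1L])
  bad_asp <- which(!is.na(df$aspect_deg) & (df$aspect_deg < 0 | df$aspect_deg >= 360))
  if (length(bad_asp))
    stop("aspect_deg outside [0, 360) at row ", bad_asp[1L])
  out_zone <- which(!is.na(df$elevation_m) &
                      (df$elevation_m < 1800 | df$elevation_m > 3000))
  if (length(out_zone))
    warning(length(out_zone), " site(s) outside the 1800-3000 m montane zone: ",
            paste(utils::head(df$site_id[out_zone], 5L), collapse = ", "))
  df
}

#' Read a scar table
#'
#' Tabular alternative to FHX input.  Requires `site_id`, `tree_id`,
#' `scar_year_start`; `scar_year_end` defaults to the start year (ranges such
#' as 1859-60 are encoded as start/end pairs differing by at most one year),
#' `season` defaults to `unknown`.
#'
#' @param path delimited text file.
#' @export
read_scar_table <- function(path) {
  df <- read_delim_table(
    path,
    required = c("site_id", "tree_id", "scar_year_start"),
    year_cols = c("scar_year_start", "scar_year_end")
  )
  if (!"scar_year_end" %in% names(df)) df$scar_year_end <- df$scar_year_start
  df$scar_year_end[is.na(df$scar_year_end)] <-
    df$scar_year_start[is.na(df$scar_year_end)]
  if (!"season" %in% names(df)) df$season <- "unknown"
  bad <- which(df$scar_year_end < df$scar_year_start |
                 df$scar_year_end - df$scar_year_start > 1L)
  if (length(bad))
    stop("scar year range must span at most one year (row ", bad[1L], ")")
  df
}

#' Validate a sites/trees/scars dataset
#'
#' Report-only consistency checks: the inputs are never modified.  Checks for
#' trees referencing unknown sites, scars referencing unknown trees, calendar
#' years outside 1400-2100, establishment after the inner ring, and duplicate
#' (tree, year) scars (a tree can record a fire at most once per year).
#'
#' @param sites,trees,scars data frames as returned by the readers.
#' @return data frame report with columns `check`, `id`, `detail`; zero rows
#'   when the dataset is consistent.
#' @export
validate_dataset <- function(sites, trees, scars) {
  rep_row <- function(check, id, detail)
    data.frame(check = check, id = as.character(id), detail = detail,
               stringsAsFactors = FALSE)
  out <- list()

  orphan_site <- setdiff(unique(trees$site_id), sites$site_id)
  for (s in orphan_site)
    out[[length(out) + 1L]] <- rep_row("orphan_site", s, "tree references unknown site")
  orphan_tree <- setdiff(unique(scars$tree_id), trees$tree_id)
  for (t in orphan_tree)
    out[[length(out) + 1L]] <- rep_row("orphan_tree", t, "scar references unknown tree")

  yr_ok <- function(y) !is.na(y) & y >= 1400 & y <= 2100
  bad_tree_yr <- trees$tree_id[!is.na(trees$inner_ring_year) &
                                 !yr_ok(trees$inner_ring_year)]
  for (t in bad_tree_yr)
    out[[length(out) + 1L]] <- rep_row("year_range", t,
                                       "inner_ring_year outside 1400-2100")
  bad_scar_yr <- scars$tree_id[!yr_ok(scars$scar_year_start)]
  for (t in unique(bad_scar_yr))
    out[[length(out) + 1L]] <- rep_row("year_range", t,
                                       "scar year outside 1400-2100")
  if ("establishment_year" %in% names(trees)) {
    bad_est <- trees$tree_id[!is.na(trees$establishment_year) &
                               !is.na(trees$inner_ring_year) &
                               trees$establishment_year > trees$inner_ring_year]
    for (t in bad_est)
      out[[length(out) + 1L]] <- rep_row("year_range", t,
                                         "establishment_year after inner_ring_year")
  }

  key <- paste(scars$tree_id, scars$scar_year_start)
  dup <- unique(key[duplicated(key)])
  for (k in dup)
    out[[length(out) + 1L]] <- rep_row("duplicate_scar", k,
                                       "tree-year scar recorded more than once")

  if (length(out)) do.call(rbind, out)
  else data.frame(check = character(), id = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

#' Collapse duplicate tree-year scars
#'
#' @param scars scar data frame.
#' @return scars with one record per (tree, start year); a warning is raised
#'   when duplicates were collapsed.
#' @export
dedupe_scars <- function(scars) {
  key <- paste(scars$tree_id, scars$scar_year_start)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate tree-year scar(s) collapsed")
    scars <- scars[!duplicated(key), , drop = FALSE]
  }
  scars
}
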