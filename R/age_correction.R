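#' Species coring-height corrections
#'
#' Median number of growth years between germination and coring height
#' (about 20 cm above the root-shoot boundary), estimated from destructively
#' sampled juveniles: 4 years for ponderosa pine (PIPO), 9 for Douglas-fir
#' (PSME), 8 for lodgepole pine (PICO), 1 for aspen (POTR) and 9 for limber
#' pine (PIFL).
#'
#' Strata overrides allow the correction to be matched to sites of similar
#' elevation and aspect: `strata` is an optional data frame with columns
#' `species`, `elevation_band`, `aspect_class`, `offset_yr` consulted before
#' the species-wide medians.
#'
#' @param overrides named integer vector of species medians to replace or add.
#' @param default offset used for species absent from the table, or `NA` to
#'   make unknown species an error.
#' @param strata optional stratum-level override table (see Details).
#' @return object of class `coring_height_table`.
#' @export
coring_height_table <- function(overrides = NULL, default = NA_integer_,
                                strata = NULL) {
  tab <- c(PIPO = 4L, PSME = 9L, PICO = 8L, POTR = 1L, PIFL = 9L)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("`overrides` must be a named vector")
    if (any(overrides < 0)) stop("coring-height offsets must be >= 0")
    tab[names(overrides)] <- as.integer(overrides)
  }
  if (!is.null(strata)) {
    need <- c("species", "elevation_band", "aspect_class", "offset_yr")
    if (!all(need %in% names(strata)))
      stop("`strata` must have columns: ", paste(need, collapse = ", "))
  }
  structure(list(species = tab, default = as.integer(default), strata = strata),
            class = "coring_height_table")
}

#' Look up a coring-height offset
#'
#' Stratum match (species + elevation band + aspect class) wins over the
#' species-wide median, which wins over the table default.
#'
#' @param table a [coring_height_table()].
#' @param species species code.
#' @param elevation_band,aspect_class optional stratum keys.
#' @return integer offset in years.
#' @export
coring_height_offset <- function(table, species, elevation_band = NA,
                                 aspect_class = NA) {
  stopifnot(inherits(table, "coring_height_table"))
  if (!is.null(table$strata) && !is.na(elevation_band) && !is.na(aspect_class)) {
    hit <- table$strata$species == species &
      table$strata$elevation_band == elevation_band &
      table$strata$aspect_class == aspect_class
    if (any(hit)) return(as.integer(table$strata$offset_yr[which(hit)[1L]]))
  }
  if (species %in% names(table$species)) return(table$species[[species]])
  if (!is.na(table$default)) return(table$default)
  stop("no coring-height offset for species '", species,
       "' and no default declared")
}

#' Pith-offset estimate from inner-ring arc geometry
#'
#' When a core misses the pith, the innermost visible rings form circular
#' arcs.  From the chord length L and arc height h of the innermost arc the
#' radius of curvature is
#' \deqn{r = h/2 + L^2 / (8h),}
#' and the number of missed rings is `r` divided by the mean width of the
#' innermost rings, rounded to the nearest integer.
#'
#' @param chord_mm chord length across the innermost arc (mm).
#' @param arc_height_mm height of the arc above the chord (mm).
#' @param mean_inner_ring_width_mm mean ring width near the core's inner end
#'   (mm/ring).
#' @return estimated missed rings (nonnegative integer).
#' @examples
#' duncan_pith_offset(20, 2, 1)  # r = 1 + 400/16 = 26 -> 26 rings
#' @export
duncan_pith_offset <- function(chord_mm, arc_height_mm, mean_inner_ring_width_mm) {
  if (any(chord_mm <= 0) || any(arc_height_mm <= 0) ||
      any(mean_inner_ring_width_mm <= 0))
    stop("pith geometry must be positive (chord, arc height, ring width)")
  if (any(arc_height_mm > chord_mm))
    stop("arc height exceeds chord length: implausible geometry")
  r <- arc_height_mm / 2 + chord_mm^2 / (8 * arc_height_mm)
  rings <- as.integer(round(r / mean_inner_ring_width_mm))
  pmax(rings, 0L)
}

#' Establishment years with exclusion rule
#'
#' Establishment year = inner-ring year minus the pith offset minus the
#' coring-height offset.  Cores with more than `max_pith_offset` (default 20)
#' years estimated to pith are flagged `excluded` and never enter downstream
#' severity metrics; the estimate is still recorded.  Trees below `min_dbh_cm`
#' (too small to core; default 4 cm) are likewise excluded.
#'
#' @param trees tree data frame with `species`, `inner_ring_year` and
#'   `pith_offset_yr` (missing pith offsets are treated as 0); an existing
#'   `coring_height_offset_yr` column overrides the table lookup.
#' @param table a [coring_height_table()].
#' @param max_pith_offset exclusion threshold on the pith offset (years).
#' @param min_dbh_cm minimum diameter for inclusion; applied only when a
#'   `dbh_cm` column is present (missing dbh is retained).
#' @return `trees` with `establishment_year`, `excluded` (logical) and
#'   `exclusion_reason` columns filled in.
#' @export
estimate_establishment_years <- function(trees, table = coring_height_table(),
                                         max_pith_offset = 20L,
                                         min_dbh_cm = 4) {
  n <- nrow(trees)
  pith <- if ("pith_offset_yr" %in% names(trees)) trees$pith_offset_yr else rep(0L, n)
  pith[is.na(pith)] <- 0L
  if (any(pith < 0)) stop("pith_offset_yr must be >= 0")
  if ("coring_height_offset_yr" %in% names(trees) &&
      !all(is.na(trees$coring_height_offset_yr))) {
    ch <- trees$coring_height_offset_yr
    miss <- is.na(ch)
    if (any(miss))
      ch[miss] <- vapply(trees$species[miss], coring_height_offset,
                         integer(1L), table = table)
  } else {
    ch <- vapply(trees$species, coring_height_offset, integer(1L), table = table)
  }
  trees$coring_height_offset_yr <- as.integer(ch)
  trees$pith_offset_yr <- as.integer(pith)
  trees$establishment_year <- as.integer(trees$inner_ring_year - pith - ch)

  excluded <- pith > max_pith_offset
  reason <- ifelse(excluded, "pith_offset_gt_threshold", NA_character_)
  if ("dbh_cm" %in% names(trees)) {
    small <- !is.na(trees$dbh_cm) & trees$dbh_cm < min_dbh_cm
    reason[small & !excluded] <- "below_min_dbh"
    excluded <- excluded | small
  }
  trees$excluded <- excluded
  trees$exclusion_reason <- reason
  trees
}
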