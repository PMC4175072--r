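#' Binarize observed burn-severity classes
#'
#' Thematic burn-severity classes 1-4 (1 = unburned/low, 2 = low,
#' 3 = moderate, 4 = high) are collapsed to the two-regime scheme used for
#' comparison with the historical map: classes 1-2 become low, classes 3-4
#' mixed, and any other value (e.g. post-fire regrowth codes) becomes nodata.
#' Idempotent: applying it to an already-binarized raster is a no-op.
#'
#' @param observed integer `fire_grid` of severity classes.
#' @return integer `fire_grid` with codes 1 (low) / 2 (mixed).
#' @export
binarize_observed <- function(observed) {
  stopifnot(is_fire_grid(observed))
  if (isTRUE(attr(observed, "binarized"))) return(observed)
  v <- as.vector(unclass(observed))
  out <- rep(NA_integer_, length(v))
  out[v %in% c(1, 2)] <- REGIME_LOW
  out[v %in% c(3, 4)] <- REGIME_MIXED
  res <- grid_like(observed, out)
  attr(res, "binarized") <- TRUE
  res
}

#' Observed-versus-historical comparison for one fire
#'
#' Within the fire perimeter, counts observed low-severity pixels (binarized
#' classes) against the expectation from the historical regime map: if a
#' fraction p of perimeter pixels is mapped as historical low severity, the
#' expected low count is N * p.  The chi-square statistic is the two-cell
#' goodness of fit `sum((O - E)^2 / E)` with 1 degree of freedom and no
#' continuity correction.  The test is flagged invalid whenever an expected
#' count is zero (e.g. a perimeter whose historical map is entirely one
#' class).  Pixels lacking either layer are dropped from both observed and
#' expected counts.
#'
#' @param observed `fire_grid` of severity classes 1-4 (or binarized codes).
#' @param historical `fire_grid` of historical regime codes (1 low, 2 mixed).
#' @param perimeter `fire_grid` (or matrix) mask of the fire perimeter.
#' @param fire_id identifier carried into the result.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return one-row data frame: `fire_id`, `n_pixels`, `observed_low_pct`,
#'   `expected_low_pct`, `chi2`, `df`, `p`, `valid`.
#' @export
compare_fire <- function(observed, historical, perimeter, fire_id = "fire",
                         correct = FALSE) {
  check_aligned(observed, historical)
  obs_bin <- binarize_observed(observed)
  per <- as.vector(unclass(perimeter)) != 0 & !is.na(as.vector(unclass(perimeter)))
  if (!any(per)) stop("empty fire perimeter")
  ob <- as.vector(unclass(obs_bin)); hi <- as.vector(unclass(historical))
  ok <- per & !is.na(ob) & !is.na(hi)
  n <- sum(ok)
  if (n == 0L) stop("no jointly classified pixels inside the perimeter")
  o_low <- sum(ob[ok] == REGIME_LOW)
  p_low <- mean(hi[ok] == REGIME_LOW)
  e_low <- n * p_low; e_mixed <- n * (1 - p_low)
  valid <- e_low > 0 && e_mixed > 0
  chi2 <- NA_real_; p <- NA_real_
  if (valid) {
    o <- c(o_low, n - o_low); e <- c(e_low, e_mixed)
    adj <- if (correct) pmax(abs(o - e) - 0.5, 0) else abs(o - e)
    chi2 <- sum(adj^2 / e)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  }
  data.frame(fire_id = fire_id, n_pixels = n,
             observed_low_pct = 100 * o_low / n,
             expected_low_pct = 100 * p_low,
             chi2 = chi2, df = 1L, p = p, valid = valid,
             stringsAsFactors = FALSE)
}

#' Severity-class proportions within a fire perimeter
#'
#' @param observed `fire_grid` of severity classes 1-4.
#' @param perimeter mask grid.
#' @return data frame with one row per class 1-4: `class`, `label`,
#'   `n_cells`, `area_ha`, `pct` (percent of classified pixels; sums to 100).
#' @export
fire_severity_proportions <- function(observed, perimeter) {
  check_aligned(observed, perimeter)
  v <- as.vector(unclass(observed))
  per <- as.vector(unclass(perimeter)) != 0 & !is.na(as.vector(unclass(perimeter)))
  ok <- per & v %in% 1:4
  if (!any(ok)) stop("no classified severity pixels inside the perimeter")
  n_tot <- sum(ok)
  labels <- c("unburned_low", "low", "moderate", "high")
  n <- vapply(1:4, function(k) sum(v[ok] == k), integer(1L))
  data.frame(class = 1:4, label = labels, n_cells = n,
             area_ha = n * cell_area_ha(observed),
             pct = 100 * n / n_tot, stringsAsFactors = FALSE)
}

#' Collapse modeled crown-activity classes
#'
#' Maps per-cell crown-activity classes to the binary scheme used in the
#' overlay: surface stays surface, torching and crowning become
#' crown-or-torch.  In intensity-only mode the crown class is ignored and
#' fireline intensity (kW/m) is banded at the approximate median intensities
#' of moderate (33,000 kW/m) and high (40,000 kW/m) severity fire: below the
#' moderate threshold is surface-equivalent, at or above it crown-or-torch
#' (cells at or above the high threshold additionally carry band `"high"`).
#'
#' @param behavior list with `crown_class` (`fire_grid` coded 1 surface,
#'   2 torch, 3 crown, or character) and `intensity_kwm`.
#' @param mode `"crown_class"` (default) or `"intensity"`.
#' @param moderate_kwm,high_kwm intensity thresholds for intensity mode.
#' @return list: `binary` (`fire_grid`, 1 = surface, 2 = crown_or_torch) and,
#'   in intensity mode, `band` (1 surface, 2 moderate, 3 high).
#' @export
classify_behavior <- function(behavior, mode = c("crown_class", "intensity"),
                              moderate_kwm = 33000, high_kwm = 40000) {
  mode <- match.arg(mode)
  if (mode == "crown_class") {
    cc <- behavior$crown_class
    stopifnot(is_fire_grid(cc))
    v <- as.vector(unclass(cc))
    out <- rep(NA_integer_, length(v))
    out[v == 1] <- 1L
    out[v %in% c(2, 3)] <- 2L
    list(binary = grid_like(cc, out))
  } else {
    fi <- behavior$intensity_kwm
    stopifnot(is_fire_grid(fi))
    v <- as.vector(unclass(fi))
    band <- rep(NA_integer_, length(v))
    band[v < moderate_kwm] <- 1L
    band[v >= moderate_kwm] <- 2L
    band[v >= high_kwm] <- 3L
    binary <- ifelse(band >= 2L, 2L, band)
    list(binary = grid_like(fi, binary), band = grid_like(fi, band))
  }
}

#' Four-way overlay of historical regime and potential fire behavior
#'
#' Partitions the jointly classified study area into the four map categories:
#' historical low with surface-fire potential (little change), historical low
#' with crown/torch potential (severity increase), historical mixed with
#' surface potential, and historical mixed with crown/torch potential.
#' Reports pixel counts, percent of classified area (summing to 100), area in
#' hectares and mean fireline intensity per category.
#'
#' @param historical `fire_grid` of regime codes (1 low, 2 mixed).
#' @param behavior list with `crown_class` and `intensity_kwm` grids.
#' @param mode passed to [classify_behavior()].
#' @return data frame with four rows: `historical`, `behavior`, `n_cells`,
#'   `pct`, `area_ha`, `mean_intensity_kwm`.
#' @export
crossmap <- function(historical, behavior, mode = "crown_class") {
  beh <- classify_behavior(behavior, mode = mode)$binary
  check_aligned(historical, beh)
  hi <- as.vector(unclass(historical)); bv <- as.vector(unclass(beh))
  fi <- if (!is.null(behavior$intensity_kwm))
    as.vector(unclass(behavior$intensity_kwm)) else rep(NA_real_, length(hi))
  ok <- !is.na(hi) & !is.na(bv)
  n_tot <- sum(ok)
  if (n_tot == 0L) stop("no jointly classified cells")
  cats <- expand.grid(historical = c("low", "mixed"),
                      behavior = c("surface", "crown_or_torch"),
                      stringsAsFactors = FALSE)
  cats <- cats[order(cats$historical, cats$behavior), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cats)), function(i) {
    hsel <- hi == match(cats$historical[i], c("low", "mixed"))
    bsel <- bv == match(cats$behavior[i], c("surface", "crown_or_torch"))
    sel <- ok & hsel & bsel
    data.frame(historical = cats$historical[i], behavior = cats$behavior[i],
               n_cells = sum(sel), pct = 100 * sum(sel) / n_tot,
               area_ha = sum(sel) * cell_area_ha(historical),
               mean_intensity_kwm = if (any(sel)) mean(fi[sel], na.rm = TRUE)
                                    else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Verify modeled fire behavior against observed severity classes
#'
#' Draws `n_points` random cells (uniform, without replacement, at cell
#' resolution) within a fire perimeter and summarizes modeled fireline
#' intensity and crown-fire occurrence within each observed severity class:
#' per-class median intensity and percent crown/torch, plus Kruskal-Wallis
#' tests (chi-square approximation with tie correction, df = k - 1) for
#' differences in intensity and crown occurrence across classes.
#' Deterministic given `seed`.
#'
#' @param observed `fire_grid` of severity classes 1-4.
#' @param behavior list with `intensity_kwm` and `crown_class` grids.
#' @param perimeter mask grid.
#' @param n_points number of random points (default 500; capped at the
#'   number of classified perimeter cells).
#' @param seed integer seed.
#' @return list: `by_class` data frame (`class`, `n`, `median_intensity_kwm`,
#'   `pct_crown`), `kw_intensity` and `kw_crown` (each `statistic`, `df`,
#'   `p`, or `NA`s with a note when fewer than two classes are present),
#'   `n_points`.
#' @export
verify_behavior <- function(observed, behavior, perimeter, n_points = 500L,
                            seed = 1L) {
  check_aligned(observed, behavior$intensity_kwm)
  v <- as.vector(unclass(observed))
  per <- as.vector(unclass(perimeter)) != 0 & !is.na(as.vector(unclass(perimeter)))
  fi <- as.vector(unclass(behavior$intensity_kwm))
  cc <- as.vector(unclass(behavior$crown_class))
  pool <- which(per & v %in% 1:4 & !is.na(fi) & !is.na(cc))
  if (length(pool) < 2L) stop("fewer than two classified perimeter cells")
  set.seed(as.integer(seed))
  pts <- if (length(pool) <= n_points) pool
         else sample(pool, n_points, replace = FALSE)
  cls <- v[pts]; ints <- fi[pts]; crown <- cc[pts] %in% c(2, 3)

  by_class <- do.call(rbind, lapply(sort(unique(cls)), function(k) {
    sel <- cls == k
    data.frame(class = k, n = sum(sel),
               median_intensity_kwm = stats::median(ints[sel]),
               pct_crown = 100 * mean(crown[sel]))
  }))

  kw <- function(values) {
    if (length(unique(cls)) < 2L)
      return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                  note = "single class present; test undefined"))
    if (length(unique(values)) < 2L)
      return(list(statistic = 0, df = length(unique(cls)) - 1L, p = 1,
                  note = "no variation in values"))
    kt <- stats::kruskal.test(values, factor(cls))
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value, note = NA_character_)
  }
  list(by_class = by_class,
       kw_intensity = kw(ints),
       kw_crown = kw(as.numeric(crown)),
       n_points = length(pts))
}
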