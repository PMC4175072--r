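#' Severity classification thresholds
#'
#' The percentage rubric used to call individual fires: a fire is low
#' severity when at least `low_remnant_min` percent of the dated trees
#' predate it (survived it) and at most `low_establish_max` percent
#' established within the post-fire window; high severity when fewer than
#' `high_remnant_max` percent predate it and more than `high_establish_min`
#' percent established after it; moderate otherwise.  A fire with no
#' establishment at all within the window is excluded (no structural
#' evidence the site burned).
#'
#' When the two metrics disagree the classes are evaluated in `precedence`
#' order (default high, then low), with moderate as the residual class.
#'
#' @param low_remnant_min,low_establish_max low-severity bounds (inclusive).
#' @param high_remnant_max,high_establish_min high-severity bounds (strict).
#' @param precedence order in which the non-residual classes are tested.
#' @export
severity_thresholds <- function(low_remnant_min = 80, low_establish_max = 20,
                                high_remnant_max = 20, high_establish_min = 80,
                                precedence = c("high", "low")) {
  stopifnot(all(precedence %in% c("high", "low")), length(precedence) == 2L)
  list(low_remnant_min = low_remnant_min, low_establish_max = low_establish_max,
       high_remnant_max = high_remnant_max, high_establish_min = high_establish_min,
       precedence = precedence)
}

#' Severity class from the two percentage metrics
#'
#' Vectorized core of [classify_fire()]: maps (percent remnant, percent
#' establishment) pairs to `low`, `moderate`, `high` or `excluded`.
#'
#' @param pct_remnant,pct_establish percentages in \[0, 100\].
#' @param thresholds a [severity_thresholds()] list.
#' @return character vector of classes.
#' @export
severity_from_percentages <- function(pct_remnant, pct_establish,
                                      thresholds = severity_thresholds()) {
  if (any(pct_remnant < 0 | pct_remnant > 100 |
          pct_establish < 0 | pct_establish > 100, na.rm = TRUE))
    stop("percentages must lie in [0, 100]")
  n <- max(length(pct_remnant), length(pct_establish))
  pct_remnant <- rep_len(pct_remnant, n)
  pct_establish <- rep_len(pct_establish, n)
  out <- rep("moderate", n)
  is_high <- pct_remnant < thresholds$high_remnant_max &
    pct_establish > thresholds$high_establish_min
  is_low <- pct_remnant >= thresholds$low_remnant_min &
    pct_establish <= thresholds$low_establish_max
  for (cls in rev(thresholds$precedence)) {
    hit <- if (cls == "high") is_high else is_low
    out[hit] <- cls
  }
  out[pct_establish == 0] <- "excluded"
  out
}

#' Classify the severity of one spreading fire at a site
#'
#' Computes the two percentage metrics over all retained dated trees at the
#' site (the denominator is constant across that site's fires):
#' percent remnant = share of trees whose establishment predates the fire
#' year; percent establishment = share of trees establishing in the
#' `(fire_year, fire_year + window]` interval.  Excluded trees (pith offset
#' over threshold, sub-minimum diameter) never enter either metric.
#'
#' When the tree table carries a `status` column and `live_only = TRUE` (the
#' default), the metrics are computed over the live-tree sample: standing
#' dead stems date fires through their scars but their death dates are
#' demographically ambiguous, so they do not enter the stand-structure
#' percentages.
#'
#' @param trees tree data frame with `establishment_year` and (optionally)
#'   `excluded`; see [estimate_establishment_years()].
#' @param fire_year calendar year of the spreading fire.
#' @param window post-fire establishment window in years (default 40).
#' @param thresholds a [severity_thresholds()] list.
#' @param live_only restrict the percentage metrics to live trees when a
#'   `status` column is present.
#' @return one-row data frame: `site_id`, `year`, `pct_remnant`,
#'   `pct_establish`, `severity`, `exclusion_reason`.
#' @export
classify_fire <- function(trees, fire_year, window = 40,
                          thresholds = severity_thresholds(),
                          live_only = TRUE) {
  keep <- !is.na(trees$establishment_year)
  if ("excluded" %in% names(trees)) keep <- keep & !trees$excluded
  if (live_only && "status" %in% names(trees)) keep <- keep & trees$status == "live"
  est <- trees$establishment_year[keep]
  n <- length(est)
  if (n == 0L)
    stop("no retained dated trees at site; cannot classify fire ", fire_year)
  pct_remnant <- 100 * sum(est < fire_year) / n
  pct_establish <- 100 * sum(est > fire_year & est <= fire_year + window) / n
  severity <- severity_from_percentages(pct_remnant, pct_establish, thresholds)
  data.frame(
    site_id = if ("site_id" %in% names(trees)) trees$site_id[1L] else NA_character_,
    year = as.integer(fire_year),
    pct_remnant = pct_remnant,
    pct_establish = pct_establish,
    severity = severity,
    exclusion_reason = ifelse(severity == "excluded", "no_establishment_40yr",
                              NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Spreading fires at a site
#'
#' Fire years evidenced by scars on at least `min_trees` distinct trees.
#' Ambiguous year ranges (e.g. 1859-60, where dormant-season scarring or
#' missing rings blur the calendar year) contribute to the start year.  With
#' `merge_window = 1`, scars in the year following an event are folded into
#' it when the earlier year contains a scar whose range spans both years or
#' the later year's scars are dormant season; the merged event is dated to
#' the earlier year.
#'
#' @param scars scar data frame for one site (`tree_id`, `scar_year_start`,
#'   optional `scar_year_end`, `season`).
#' @param min_trees minimum distinct scarred trees per event (default 2).
#' @param merge_window 0 (no merging) or 1.
#' @return data frame: `site_id`, `year`, `n_trees_scarred`, sorted by year.
#' @export
find_spreading_fires <- function(scars, min_trees = 2L, merge_window = 0L) {
  if (min_trees < 1L) stop("min_trees must be >= 1")
  if (!merge_window %in% c(0L, 1L)) stop("merge_window must be 0 or 1")
  empty <- data.frame(site_id = character(), year = integer(),
                      n_trees_scarred = integer(), stringsAsFactors = FALSE)
  if (is.null(scars) || nrow(scars) == 0L) return(empty)
  if (length(unique(scars$site_id)) > 1L)
    stop("find_spreading_fires expects scars from a single site")
  if (!"scar_year_end" %in% names(scars)) scars$scar_year_end <- scars$scar_year_start
  if (!"season" %in% names(scars)) scars$season <- "unknown"

  event_year <- scars$scar_year_start
  if (merge_window == 1L) {
    yrs <- sort(unique(event_year))
    consumed <- logical(length(yrs))
    for (i in seq_along(yrs)) {
      if (consumed[i]) next
      y <- yrs[i]
      j <- match(y + 1L, yrs)
      if (is.na(j)) next
      spans <- any(event_year == y & scars$scar_year_end >= y + 1L)
      dormant_next <- any(event_year == y + 1L & scars$season == "dormant")
      if (spans || dormant_next) {
        event_year[scars$scar_year_start == y + 1L] <- y
        consumed[j] <- TRUE
      }
    }
  }

  tab <- tapply(scars$tree_id, event_year, function(x) length(unique(x)))
  years <- as.integer(names(tab))
  keep <- tab >= min_trees
  if (!any(keep)) return(empty)
  data.frame(site_id = scars$site_id[1L], year = years[keep],
             n_trees_scarred = as.integer(tab[keep]),
             stringsAsFactors = FALSE)[order(years[keep]), , drop = FALSE]
}

#' Mean fire interval
#'
#' Mean of the intervals between successive spreading-fire years.
#'
#' @param years fire years (duplicates are collapsed).
#' @return mean interval in years, or `NA` when fewer than two distinct
#'   fire years are available.
#' @examples
#' mean_fire_interval(c(1700, 1712, 1730, 1745))  # 15
#' @export
mean_fire_interval <- function(years) {
  years <- sort(unique(years))
  if (length(years) < 2L) return(NA_real_)
  mean(diff(years))
}

#' Drop unsupported early fires at a site
#'
#' Fires that precede the site's earliest moderate- or high-severity call and
#' are not associated with an establishment pulse (more than `pulse_threshold`
#' percent of the site's trees) are re-marked excluded: older-tree mortality
#' and later severe fire make their severity estimate unreliable.
#'
#' @param calls per-fire calls for one site ([classify_fire()] rows), any order.
#' @param pulse_threshold establishment pulse threshold in percent (default 20).
#' @return `calls` sorted by year with the affected rows re-marked
#'   (`severity = "excluded"`, reason `pre_mixed_no_pulse`).
#' @export
apply_sequence_exclusions <- function(calls, pulse_threshold = 20) {
  if (nrow(calls) == 0L) return(calls)
  calls <- calls[order(calls$year), , drop = FALSE]
  mh <- calls$severity %in% c("moderate", "high")
  if (!any(mh)) return(calls)
  trigger_year <- min(calls$year[mh])
  hit <- calls$year < trigger_year & calls$severity != "excluded" &
    calls$pct_establish <= pulse_threshold
  calls$severity[hit] <- "excluded"
  calls$exclusion_reason[hit] <- "pre_mixed_no_pulse"
  calls
}

#' Assign a site-level fire regime
#'
#' A site has a low-severity-only regime when every retained fire call is low
#' severity and spreading fires were frequent (MFI below `mfi_frequent`,
#' default 30 years).  Otherwise the regime is mixed: `mixed_with_high` when
#' any retained call is high severity, `mixed_no_high` when the evidence
#' stops at moderate.
#'
#' @param calls per-fire calls for one site, after sequence exclusions.
#' @param mfi mean fire interval over the site's spreading fires (`NA` when
#'   undefined).
#' @param mfi_frequent frequent-fire threshold in years.
#' @return one-row data frame: `site_id`, `regime`, `mfi_yr`,
#'   `n_spreading_fires`, `n_retained_calls`.
#' @export
classify_site_regime <- function(calls, mfi, mfi_frequent = 30) {
  retained <- calls[calls$severity %in% c("low", "moderate", "high"), ,
                    drop = FALSE]
  if (nrow(retained) == 0L)
    stop("site unclassifiable: no retained fire-severity calls")
  regime <- if (all(retained$severity == "low") && !is.na(mfi) &&
                mfi < mfi_frequent) {
    "low_only"
  } else if (any(retained$severity == "high")) {
    "mixed_with_high"
  } else {
    "mixed_no_high"
  }
  data.frame(site_id = calls$site_id[1L], regime = regime, mfi_yr = mfi,
             n_spreading_fires = nrow(calls), n_retained_calls = nrow(retained),
             stringsAsFactors = FALSE)
}

#' Composite fire chronology across sites
#'
#' Per calendar year: the number of recorder sites (sites with at least
#' `min_recorder_trees` trees in recorder status, i.e. between their first
#' scar and their last recorded year) and the number of sites recording a
#' spreading fire that year, plus the percentage recording.  The percentage
#' is `NA` in years with no recorder sites.
#'
#' @param scars scar records across sites.
#' @param tree_last optional data frame `tree_id`, `last_year` giving each
#'   tree's death/bark date; trees absent from it record through `end_year`.
#' @param end_year last year of the chronology (default: latest scar year).
#' @param min_recorder_trees minimum recorder trees for a site to count as
#'   available (default 2).
#' @param min_trees minimum scarred trees defining a spreading fire.
#' @return data frame: `year`, `n_recorder_sites`, `n_sites_recording`,
#'   `pct_recording`.
#' @export
recorder_sites_by_year <- function(scars, tree_last = NULL, end_year = NULL,
                                   min_recorder_trees = 2L, min_trees = 2L) {
  if (nrow(scars) == 0L)
    return(data.frame(year = integer(), n_recorder_sites = integer(),
                      n_sites_recording = integer(), pct_recording = numeric()))
  if (is.null(end_year)) end_year <- max(scars$scar_year_start)
  first_scar <- tapply(scars$scar_year_start,
                       paste(scars$site_id, scars$tree_id, sep = "\r"), min)
  keys <- strsplit(names(first_scar), "\r", fixed = TRUE)
  tree_site <- vapply(keys, `[`, character(1L), 1L)
  tree_id <- vapply(keys, `[`, character(1L), 2L)
  last <- rep(as.integer(end_year), length(tree_id))
  if (!is.null(tree_last)) {
    m <- match(tree_id, tree_last$tree_id)
    last[!is.na(m)] <- tree_last$last_year[m[!is.na(m)]]
  }
  years <- seq.int(min(first_scar), end_year)

  n_recorder_sites <- vapply(years, function(y) {
    rec <- first_scar <= y & last >= y
    sum(tapply(rec, tree_site, sum) >= min_recorder_trees)
  }, integer(1L))

  key_sy <- paste(scars$site_id, scars$scar_year_start)
  trees_per_sy <- tapply(scars$tree_id, key_sy, function(x) length(unique(x)))
  spread <- names(trees_per_sy)[trees_per_sy >= min_trees]
  spread_year <- as.integer(sub("^.* ", "", spread))
  n_sites_recording <- vapply(years, function(y) sum(spread_year == y), integer(1L))

  pct <- ifelse(n_recorder_sites > 0, 100 * n_sites_recording / n_recorder_sites,
                NA_real_)
  data.frame(year = years, n_recorder_sites = n_recorder_sites,
             n_sites_recording = n_sites_recording, pct_recording = pct)
}

#' Widespread fire years
#'
#' Years in which spreading fires were recorded at `min_sites` or more sites.
#'
#' @param chronology output of [recorder_sites_by_year()].
#' @param min_sites threshold (default 4).
#' @return integer vector of years.
#' @export
widespread_fire_years <- function(chronology, min_sites = 4L) {
  chronology$year[chronology$n_sites_recording >= min_sites]
}

#' Establishment histogram in fixed-width bins
#'
#' Proportion of tree establishment dates per `bin`-year bin (default 20),
#' optionally split by a grouping factor (e.g. site regime).  Bins are
#' `[origin + k*bin, origin + (k+1)*bin)`.
#'
#' @param establishment_years integer vector of establishment years.
#' @param bin bin width in years.
#' @param origin bin origin; defaults to the greatest multiple of `bin` not
#'   exceeding the earliest year.
#' @param group optional grouping vector, recycled against the years.
#' @return data frame: `group`, `bin_start`, `n`, `proportion`; proportions
#'   sum to 1 within each group.
#' @export
establishment_histogram <- function(establishment_years, bin = 20L,
                                    origin = NULL, group = NULL) {
  ok <- !is.na(establishment_years)
  if (!any(ok)) {
    warning("no establishment years; empty histogram")
    return(data.frame(group = character(), bin_start = integer(), n = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  }
  years <- establishment_years[ok]
  grp <- if (is.null(group)) rep("all", length(ok)) else rep_len(group, length(ok))
  grp <- grp[ok]
  if (is.null(origin)) origin <- bin * floor(min(years) / bin)
  starts <- origin + bin * floor((years - origin) / bin)
  out <- lapply(unique(grp), function(g) {
    s <- starts[grp == g]
    tab <- table(s)
    data.frame(group = g, bin_start = as.integer(names(tab)),
               n = as.integer(tab), proportion = as.integer(tab) / length(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full site-level reconstruction pipeline
#'
#' For each site: detect spreading fires before the historical cutoff,
#' classify each fire's severity, apply the sequence exclusions, compute the
#' mean fire interval and assign the site regime.  Sites with no spreading
#' fires or no retained calls are reported as unclassified rather than
#' erroring the batch.
#'
#' @param trees corrected tree table ([estimate_establishment_years()]).
#' @param scars scar records across sites.
#' @param cutoff_year historical cutoff; only fires strictly before it are
#'   analyzed (default 1920, circa effective fire exclusion).
#' @param window,min_trees,merge_window,pulse_threshold,mfi_frequent see the
#'   individual operations.
#' @param thresholds a [severity_thresholds()] list.
#' @return list with `calls` (per-fire classifications across sites),
#'   `regimes` (per-site regime table; `regime` is `NA` with a `note` for
#'   unclassifiable sites) and `chronology` ([recorder_sites_by_year()]).
#' @export
reconstruct_site_regimes <- function(trees, scars, cutoff_year = 1920,
                                     window = 40, min_trees = 2L,
                                     merge_window = 0L, pulse_threshold = 20,
                                     mfi_frequent = 30,
                                     thresholds = severity_thresholds(),
                                     live_only = TRUE) {
  scars <- dedupe_scars(scars)
  site_ids <- sort(unique(trees$site_id))
  calls_list <- list(); regimes_list <- list()
  for (sid in site_ids) {
    st <- trees[trees$site_id == sid, , drop = FALSE]
    ss <- scars[scars$site_id == sid, , drop = FALSE]
    fires <- find_spreading_fires(ss, min_trees = min_trees,
                                  merge_window = merge_window)
    fires <- fires[fires$year < cutoff_year, , drop = FALSE]
    if (nrow(fires) == 0L) {
      regimes_list[[sid]] <- data.frame(site_id = sid, regime = NA_character_,
                                        mfi_yr = NA_real_, n_spreading_fires = 0L,
                                        n_retained_calls = 0L,
                                        note = "no_spreading_fires",
                                        stringsAsFactors = FALSE)
      next
    }
    calls <- tryCatch(
      do.call(rbind, lapply(fires$year, function(y)
        classify_fire(st, y, window = window, thresholds = thresholds,
                      live_only = live_only))),
      error = function(e) NULL)
    if (is.null(calls)) {
      regimes_list[[sid]] <- data.frame(site_id = sid, regime = NA_character_,
                                        mfi_yr = mean_fire_interval(fires$year),
                                        n_spreading_fires = nrow(fires),
                                        n_retained_calls = 0L,
                                        note = "no_dated_trees",
                                        stringsAsFactors = FALSE)
      next
    }
    calls <- apply_sequence_exclusions(calls, pulse_threshold = pulse_threshold)
    mfi <- mean_fire_interval(fires$year)
    reg <- tryCatch(
      cbind(classify_site_regime(calls, mfi, mfi_frequent = mfi_frequent),
            note = NA_character_, stringsAsFactors = FALSE),
      error = function(e)
        data.frame(site_id = sid, regime = NA_character_, mfi_yr = mfi,
                   n_spreading_fires = nrow(fires), n_retained_calls = 0L,
                   note = "no_retained_calls", stringsAsFactors = FALSE))
    calls_list[[sid]] <- calls
    regimes_list[[sid]] <- reg
  }
  list(calls = if (length(calls_list)) do.call(rbind, c(calls_list,
                                                        make.row.names = FALSE))
       else NULL,
       regimes = do.call(rbind, c(regimes_list, make.row.names = FALSE)),
       chronology = recorder_sites_by_year(scars, min_trees = min_trees))
}
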