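#' Parameters for simulating a site-level fire and stand history
#'
#' Describes the generative regime at one site.  Fire years follow a Weibull
#' renewal process (shape 2 by default: quasi-periodic intervals, as
#' fire-interval data show) with mean interval `mean_interval_yr` (15 years
#' for the low-severity regime, 45 for mixed), running from the start of
#' `sim_span` until fire exclusion (`fire_exclusion_year`, default 1920).
#' Under the low-severity regime every fire is low severity; under the mixed
#' regime each fire's severity is drawn from `severity_mix`.  Site-level
#' canopy mortality per fire is uniform within the class-specific
#' `canopy_mortality` range; juvenile trees (younger than `juvenile_age_yr`)
#' are additionally killed with probability `juvenile_kill_prob` by any fire.
#'
#' The stand starts from an old-growth initiation cohort established over
#' `init_cohort_span` (predating the simulated fire record), with sparse
#' background establishment at `background_establish_rate` trees/yr and, after
#' moderate or high-severity fires, an establishment pulse of mean size
#' `pulse_size` whose dates decay exponentially (mean `pulse_decay_yr`) and
#' fall within 30 years of the fire.  All trees face a constant background
#' mortality hazard (`background_hazard`, default 0.3 percent/yr).  Sampling
#' (default year 2012) draws `n_sampled_trees` stems at least
#' `min_sample_age_yr` old from the standing pool: live trees plus dead stems
#' that died within `snag_persistence_yr` of sampling (datable remnant wood).
#'
#' @param regime `"low_only"` or `"mixed"`.
#' @param mean_interval_yr mean fire interval (years); defaults 15 (low) / 45
#'   (mixed).
#' @param interval_shape Weibull shape of the renewal process.
#' @param scar_prob probability an adult survivor records a scar per fire.
#' @param severity_mix probabilities over (low, moderate, high) per fire in
#'   the mixed regime.
#' @param canopy_mortality list of `c(min, max)` mortality fractions by
#'   severity class.
#' @param background_establish_rate surviving-establishment rate (trees/yr).
#' @param pulse_size,pulse_decay_yr post-fire establishment pulse (mean
#'   cohort size; exponential decay of establishment dates).
#' @param init_cohort_size,init_cohort_span stand-initiation cohort.
#' @param background_hazard annual background mortality probability.
#' @param juvenile_age_yr,juvenile_kill_prob juvenile fire-mortality model.
#' @param sim_span,fire_exclusion_year,sampling_year timeline (calendar years).
#' @param n_sampled_trees,min_sample_age_yr,snag_persistence_yr sampling
#'   model: the age-structure sample is drawn from live stems, while up to
#'   `n_scar_trees` fire-scarred dead stems that died within
#'   `snag_persistence_yr` of sampling (datable remnant wood) contribute
#'   additional scar series.
#' @param n_scar_trees cap on collected dead scar-bearing stems per site.
#' @param pith_offset_max usual upper bound of simulated pith offsets;
#'   a small fraction of cores (3 percent) exceed the 20-ring exclusion
#'   threshold to exercise the exclusion rule.
#' @return list of class `regime_params`.
#' @export
regime_params <- function(regime = c("low_only", "mixed"),
                          mean_interval_yr = NULL,
                          interval_shape = 2,
                          scar_prob = 0.5,
                          severity_mix = c(low = 0.4, moderate = 0.3, high = 0.3),
                          canopy_mortality = list(low = c(0, 0.1),
                                                  moderate = c(0.25, 0.75),
                                                  high = c(0.85, 1.0)),
                          background_establish_rate = NULL,
                          pulse_size = 60, pulse_decay_yr = 10,
                          init_cohort_size = NULL,
                          init_cohort_span = c(1400, 1480),
                          background_hazard = 0.003,
                          juvenile_age_yr = 20, juvenile_kill_prob = 0.8,
                          sim_span = c(1500, 2012),
                          fire_exclusion_year = 1920,
                          sampling_year = 2012,
                          n_sampled_trees = 50,
                          min_sample_age_yr = 20,
                          snag_persistence_yr = 250,
                          n_scar_trees = 25,
                          pith_offset_max = 6) {
  regime <- match.arg(regime)
  if (is.null(mean_interval_yr))
    mean_interval_yr <- if (regime == "low_only") 15 else 45
  if (is.null(background_establish_rate))
    background_establish_rate <- if (regime == "low_only") 0.12 else 0.1
  if (is.null(init_cohort_size))
    init_cohort_size <- if (regime == "low_only") 2200 else 100
  if (mean_interval_yr <= 0) stop("mean interval must be positive")
  if (length(severity_mix) != 3L)
    stop("severity_mix must give probabilities for (low, moderate, high)")
  if (is.null(names(severity_mix)))
    names(severity_mix) <- c("low", "moderate", "high")
  if (any(severity_mix < 0)) stop("severity_mix probabilities must be >= 0")
  severity_mix <- severity_mix / sum(severity_mix)
  as.list(environment())
}

weibull_scale_from_mean <- function(mean, shape) mean / gamma(1 + 1 / shape)

#' Simulate one site's fire and stand history
#'
#' Runs the renewal-process fire history and stand demography described in
#' [regime_params()] and returns the observable dataset: the sampled tree
#' table (with raw inner-ring years and pith/coring-height offsets, so the
#' age-correction step can be exercised downstream), the fire-scar records of
#' the sampled trees, the true fire history, and the generating regime.
#' A pure function of `(params, seed)`.
#'
#' @param params a [regime_params()] list.
#' @param seed integer seed.
#' @param site_id site identifier stamped on all records.
#' @return list: `trees`, `scars`, `fires` (true fire years and severities),
#'   `regime` (the generating regime, `low_only` or `mixed`).
#' @export
simulate_site_history <- function(params, seed = 1L, site_id = "site1") {
  set.seed(as.integer(seed))
  p <- params
  span0 <- p$sim_span[1L]

  # renewal-process fire years, stopped at fire exclusion
  scale <- weibull_scale_from_mean(p$mean_interval_yr, p$interval_shape)
  fire_years <- integer()
  t <- span0
  repeat {
    t <- t + max(1, round(stats::rweibull(1L, p$interval_shape, scale)))
    if (t >= p$fire_exclusion_year) break
    fire_years <- c(fire_years, t)
  }
  sev <- if (p$regime == "low_only") rep("low", length(fire_years))
         else sample(names(p$severity_mix), length(fire_years), replace = TRUE,
                     prob = p$severity_mix)

  # establishment: initiation cohort + background + post-fire pulses
  est <- floor(stats::runif(p$init_cohort_size, p$init_cohort_span[1L],
                            p$init_cohort_span[2L] + 1))
  n_bg <- stats::rpois(1L, p$background_establish_rate *
                         (p$sampling_year - span0))
  est <- c(est, floor(stats::runif(n_bg, span0, p$sampling_year + 1)))
  for (i in which(sev %in% c("moderate", "high"))) {
    n_p <- stats::rpois(1L, p$pulse_size)
    lag <- pmin(1 + floor(stats::rexp(n_p, 1 / p$pulse_decay_yr)), 30)
    est <- c(est, fire_years[i] + lag)
  }
  est <- as.integer(est[est <= p$sampling_year])
  n <- length(est)

  # background mortality: geometric lifetime at constant annual hazard
  death <- est + stats::rgeom(n, p$background_hazard) + 1L

  # fire mortality, chronological
  for (i in seq_along(fire_years)) {
    fy <- fire_years[i]
    alive <- est <= fy & death > fy   # germinants of the fire year are exposed
    if (!any(alive)) next
    mrange <- p$canopy_mortality[[sev[i]]]
    mfrac <- stats::runif(1L, mrange[1L], mrange[2L])
    kill_p <- ifelse(fy - est < p$juvenile_age_yr,
                     pmax(mfrac, p$juvenile_kill_prob), mfrac)
    killed <- alive & stats::runif(n) < kill_p
    death[killed] <- fy
  }

  # age-structure sample: live stems old enough to core
  age_at_end <- pmin(death, p$sampling_year) - est
  live_pool <- which(death > p$sampling_year &
                       age_at_end >= p$min_sample_age_yr)
  if (!length(live_pool))
    stop("stand extinction: no live sampleable trees at ", site_id,
         "; lower mortality or raise establishment in the parameters")
  live_sample <- if (length(live_pool) <= p$n_sampled_trees) live_pool
                 else sample(live_pool, p$n_sampled_trees, replace = FALSE)

  # scar-bearing dead wood: stems that died recently enough to date and that
  # were adult during at least one fire
  witnessed_any <- rep(FALSE, n)
  for (fy in fire_years)
    witnessed_any <- witnessed_any | (est < fy - 10 & death > fy)
  dead_pool <- which(death <= p$sampling_year &
                       death > p$sampling_year - p$snag_persistence_yr &
                       age_at_end >= p$min_sample_age_yr &
                       witnessed_any)
  dead_sample <- if (length(dead_pool) <= p$n_scar_trees) dead_pool
                 else sample(dead_pool, p$n_scar_trees, replace = FALSE)

  sampled <- sort(c(live_sample, dead_sample))
  ns <- length(sampled)

  species_pool <- if (p$regime == "low_only") {
    c("PIPO")
  } else c("PIPO", "PSME", "PICO", "POTR", "PIFL")
  species_prob <- if (p$regime == "low_only") 1 else c(.4, .25, .2, .1, .05)
  species <- sample(species_pool, ns, replace = TRUE, prob = species_prob)

  ch_tab <- coring_height_table()
  ch <- vapply(species, coring_height_offset, integer(1L), table = ch_tab)
  pith <- sample(0:p$pith_offset_max, ns, replace = TRUE)
  deep <- stats::runif(ns) < 0.03          # occasional core far from pith
  pith[deep] <- sample(21:26, sum(deep), replace = TRUE)

  est_s <- est[sampled]; death_s <- death[sampled]
  live <- death_s > p$sampling_year
  age_s <- pmin(death_s, p$sampling_year) - est_s
  trees <- data.frame(
    site_id = site_id,
    tree_id = sprintf("%s_t%03d", site_id, seq_len(ns)),
    species = species,
    inner_ring_year = as.integer(est_s + pith + ch),
    pith_offset_yr = as.integer(pith),
    coring_height_offset_yr = as.integer(ch),
    status = ifelse(live, "live", "dead"),
    dbh_cm = round(4 + 0.12 * pmax(age_s - p$min_sample_age_yr, 0) +
                     abs(stats::rnorm(ns, 0, 2)), 1),
    stringsAsFactors = FALSE
  )

  # scars: adult survivors of a fire record it with probability scar_prob
  scar_rows <- list()
  for (i in seq_along(fire_years)) {
    fy <- fire_years[i]
    witness <- est_s < fy - 10 & death_s > fy
    hit <- witness & stats::runif(ns) < p$scar_prob
    if (any(hit)) {
      scar_rows[[length(scar_rows) + 1L]] <- data.frame(
        site_id = site_id,
        tree_id = trees$tree_id[hit],
        scar_year_start = fy, scar_year_end = fy,
        season = sample(c("dormant", "unknown"), sum(hit), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  scars <- if (length(scar_rows)) do.call(rbind, scar_rows)
           else data.frame(site_id = character(), tree_id = character(),
                           scar_year_start = integer(), scar_year_end = integer(),
                           season = character(), stringsAsFactors = FALSE)

  list(trees = trees, scars = scars,
       fires = data.frame(year = fire_years, severity = sev,
                          stringsAsFactors = FALSE),
       regime = if (p$regime == "low_only") "low_only" else "mixed")
}

#' Simulate a multi-site dataset
#'
#' Convenience wrapper: `n_low` low-severity-regime and `n_mixed`
#' mixed-regime sites, each simulated with its own seed derived from `seed`.
#'
#' @param n_low,n_mixed site counts per generating regime.
#' @param seed master seed; site i uses `seed * 1000 + i` (kept below 2^31).
#' @param low_params,mixed_params [regime_params()] lists.
#' @return list: `trees`, `scars` (bound across sites), `sites` data frame
#'   with `site_id` and `true_regime`.
#' @export
simulate_site_set <- function(n_low = 100L, n_mixed = 100L, seed = 1L,
                              low_params = regime_params("low_only"),
                              mixed_params = regime_params("mixed")) {
  n <- n_low + n_mixed
  trees <- list(); scars <- list(); sites <- list()
  for (i in seq_len(n)) {
    is_low <- i <= n_low
    sid <- sprintf("s%03d", i)
    h <- simulate_site_history(if (is_low) low_params else mixed_params,
                               seed = (as.integer(seed) * 1000L + i) %% .Machine$integer.max,
                               site_id = sid)
    trees[[i]] <- h$trees; scars[[i]] <- h$scars
    sites[[i]] <- data.frame(site_id = sid, true_regime = h$regime,
                             stringsAsFactors = FALSE)
  }
  list(trees = do.call(rbind, c(trees, make.row.names = FALSE)),
       scars = do.call(rbind, c(scars, make.row.names = FALSE)),
       sites = do.call(rbind, c(sites, make.row.names = FALSE)))
}

#' Parameters for a synthetic landscape
#'
#' @param nrow,ncol grid shape.
#' @param cell_m cell size (m).
#' @param elev_range elevation bounds of the montane zone (1800-3000 m); the
#'   field is clipped into this range.
#' @param elev_mean,elev_sd target mean and standard deviation (m) the
#'   smoothed random field is standardized to before clipping, fixing the
#'   landscape's hypsometry across seeds.
#' @param smooth_sigma Gaussian smoothing length of the elevation field, in
#'   cells.
#' @param rule the generating [regime_rule()].
#' @param label_noise probability a site's regime label is flipped.
#' @param n_sites number of site locations sampled (uniform, without
#'   replacement, over cells with defined terrain).
#' @export
landscape_params <- function(nrow = 120L, ncol = 120L, cell_m = 30,
                             elev_range = c(1800, 3000),
                             elev_mean = 2400, elev_sd = 250,
                             smooth_sigma = 10,
                             rule = regime_rule(), label_noise = 0.05,
                             n_sites = 500L) {
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5)")
  as.list(environment())
}

smooth_field <- function(m, sigma) {
  # separable Gaussian smoothing with edge renormalization
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    out <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
    out[(half + 1):(half + length(v))]
  }
  num <- apply(m, 2L, conv1); num <- t(apply(num, 1L, conv1))
  one <- matrix(1, nrow(m), ncol(m))
  den <- apply(one, 2L, conv1); den <- t(apply(den, 1L, conv1))
  num / den
}

#' Simulate a landscape: covariates, true regime raster, labeled sites
#'
#' Generates a smoothed random elevation field rescaled to the montane zone,
#' derives terrain covariates from it, maps the true regime with
#' [apply_rule()], and samples site locations whose labels equal the mapped
#' regime apart from independent flips with probability `label_noise`.
#' A pure function of `(params, seed)`.
#'
#' @param params a [landscape_params()] list.
#' @param seed integer seed.
#' @return list: `covariates` (named list of `fire_grid`s including
#'   `elevation_m` and `slope_deg`), `regime` (true regime raster),
#'   `sites` (data frame of site covariates with `label` and `true_regime`).
#' @export
simulate_landscape <- function(params = landscape_params(), seed = 1L) {
  set.seed(as.integer(seed))
  p <- params
  if (p$n_sites > p$nrow * p$ncol) stop("more sites than grid cells")
  noise <- matrix(stats::rnorm(p$nrow * p$ncol), p$nrow, p$ncol)
  z <- smooth_field(noise, p$smooth_sigma)
  z <- (z - mean(z)) / stats::sd(z)
  elev <- fire_grid(pmin(pmax(p$elev_mean + z * p$elev_sd,
                              p$elev_range[1L]), p$elev_range[2L]),
                    cell_m = p$cell_m)
  terr <- derive_terrain(elev)
  cov <- c(list(elevation_m = elev), terr)
  regime <- apply_rule(cov, p$rule)

  complete <- !is.na(unclass(terr$slope_deg)) &
    !is.na(unclass(terr$aspect_sin)) & !is.na(unclass(terr$curvature))
  ok_cells <- which(complete)
  if (p$n_sites > length(ok_cells)) stop("more sites than usable cells")
  cells <- sample(ok_cells, p$n_sites, replace = FALSE)
  true_lab <- c("low", "mixed")[unclass(regime)[cells]]
  flip <- stats::runif(p$n_sites) < p$label_noise
  lab <- ifelse(flip, ifelse(true_lab == "low", "mixed", "low"), true_lab)
  sites <- data.frame(
    site_id = sprintf("L%04d", seq_len(p$n_sites)),
    cell = cells,
    elevation_m = unclass(elev)[cells],
    slope_deg = unclass(terr$slope_deg)[cells],
    aspect_sin = unclass(terr$aspect_sin)[cells],
    aspect_arcsine = unclass(terr$aspect_arcsine)[cells],
    curvature = unclass(terr$curvature)[cells],
    true_regime = true_lab,
    label = lab,
    stringsAsFactors = FALSE
  )
  list(covariates = cov, regime = regime, sites = sites)
}

#' Simulate an observed burn-severity raster
#'
#' Within the perimeter, each cell's binarized observed severity matches the
#' historical regime raster with probability `concordance`; the thematic
#' class is then drawn uniformly within the matching pair ({1,2} for low,
#' {3,4} for mixed).  Outside the perimeter the raster is nodata.
#'
#' @param regime historical regime `fire_grid` (1 low, 2 mixed).
#' @param perimeter mask grid.
#' @param concordance probability in \[0, 1\] of binary agreement.
#' @param seed integer seed.
#' @return integer `fire_grid` of classes 1-4.
#' @export
simulate_observed_fire <- function(regime, perimeter, concordance = 0.8,
                                   seed = 1L) {
  stopifnot(concordance >= 0, concordance <= 1)
  check_aligned(regime, perimeter)
  set.seed(as.integer(seed))
  per <- as.vector(unclass(perimeter)) != 0 &
    !is.na(as.vector(unclass(perimeter)))
  reg <- as.vector(unclass(regime))
  idx <- which(per & !is.na(reg))
  if (!length(idx)) stop("empty fire perimeter")
  match_hist <- stats::runif(length(idx)) < concordance
  bin <- ifelse(match_hist, reg[idx], 3L - reg[idx])   # 1 <-> 2 flip
  cls <- ifelse(bin == REGIME_LOW,
                sample(1:2, length(idx), replace = TRUE),
                sample(3:4, length(idx), replace = TRUE))
  out <- rep(NA_integer_, length(reg))
  out[idx] <- as.integer(cls)
  grid_like(regime, out)
}

#' Simulate modeled fire behavior over a regime raster
#'
#' Crown-activity class is drawn per cell with regime-dependent probability
#' of crown/torch fire; fireline intensity is lognormal with the location
#' parameter set so the class means default to 14,020 kW/m for surface cells
#' and 43,620 kW/m for crown/torch cells.
#'
#' @param regime historical regime `fire_grid`.
#' @param seed integer seed.
#' @param p_crown named probabilities of crown/torch behavior given regime
#'   (`low`, `mixed`).
#' @param mean_surface_kwm,mean_crown_kwm target mean intensities (kW/m).
#' @param sdlog lognormal log-scale standard deviation.
#' @param p_torch probability a crown/torch cell is torching (class 2)
#'   rather than active crown (class 3).
#' @return list of aligned grids: `crown_class` (1 surface, 2 torch,
#'   3 crown) and `intensity_kwm`.
#' @export
simulate_behavior <- function(regime, seed = 1L,
                              p_crown = c(low = 0.3, mixed = 0.8),
                              mean_surface_kwm = 14020,
                              mean_crown_kwm = 43620,
                              sdlog = 0.5, p_torch = 0.1) {
  set.seed(as.integer(seed))
  reg <- as.vector(unclass(regime))
  n <- length(reg)
  crown <- rep(NA_integer_, n)
  fi <- rep(NA_real_, n)
  ok <- !is.na(reg)
  pc <- ifelse(reg[ok] == REGIME_LOW, p_crown[["low"]], p_crown[["mixed"]])
  is_crown <- stats::runif(sum(ok)) < pc
  cls <- ifelse(is_crown,
                ifelse(stats::runif(sum(ok)) < p_torch, 2L, 3L), 1L)
  mu <- ifelse(is_crown, log(mean_crown_kwm), log(mean_surface_kwm)) - sdlog^2 / 2
  crown[ok] <- cls
  fi[ok] <- stats::rlnorm(sum(ok), mu, sdlog)
  list(crown_class = grid_like(regime, crown),
       intensity_kwm = grid_like(regime, fi))
}
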