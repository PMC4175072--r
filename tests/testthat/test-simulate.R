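test_that("site histories are pure functions of (params, seed)", {
  p <- regime_params("mixed")
  a <- simulate_site_history(p, seed = 9, site_id = "x")
  b <- simulate_site_history(p, seed = 9, site_id = "x")
  expect_identical(a, b)
  c_ <- simulate_site_history(p, seed = 10, site_id = "x")
  expect_false(identical(a$fires, c_$fires))
})

test_that("generated datasets pass validation with an empty report", {
  d <- simulate_site_set(3, 3, seed = 4)
  sites <- data.frame(site_id = unique(d$trees$site_id))
  rep <- validate_dataset(sites, d$trees, d$scars)
  expect_equal(nrow(rep), 0L)
})

test_that("realized fire counts sit inside the renewal-process envelope", {
  # envelope: 10,000 replicate renewal paths over the same span, computed
  # directly from the interval distribution
  p <- regime_params("low_only", mean_interval_yr = 15,
                     sim_span = c(1600, 2012), fire_exclusion_year = 1920)
  scale <- 15 / gamma(1 + 1 / 2)
  set.seed(99)
  counts <- replicate(10000, {
    t <- 1600; k <- 0
    repeat {
      t <- t + max(1, round(rweibull(1, 2, scale)))
      if (t >= 1920) break
      k <- k + 1
    }
    k
  })
  lo <- quantile(counts, 0.005); hi <- quantile(counts, 0.995)
  for (s in 1:5) {
    h <- simulate_site_history(p, seed = s)
    expect_gte(nrow(h$fires), lo)
    expect_lte(nrow(h$fires), hi)
  }
})

test_that("a stand-replacing last fire forces a high-severity call", {
  # all fires high, total mortality, survivor-only sampling: every sampled
  # tree postdates the last fire
  p <- regime_params("mixed", severity_mix = c(low = 0, moderate = 0, high = 1),
                     canopy_mortality = list(low = c(0, 0), moderate = c(1, 1),
                                             high = c(1, 1)),
                     background_establish_rate = 0,
                     snag_persistence_yr = 0)
  h <- simulate_site_history(p, seed = 3, site_id = "hs")
  last_fire <- max(h$fires$year)
  tr <- estimate_establishment_years(h$trees)
  expect_true(all(tr$establishment_year > last_fire))
  call <- classify_fire(tr, last_fire)
  expect_equal(call$severity, "high")
})

test_that("landscape labels equal the mapped rule when noise is zero", {
  L0 <- simulate_landscape(landscape_params(nrow = 60, ncol = 60,
                                            label_noise = 0, n_sites = 200),
                           seed = 2)
  expect_identical(L0$sites$label, L0$sites$true_regime)
  # same seed, same grids
  L0b <- simulate_landscape(landscape_params(nrow = 60, ncol = 60,
                                             label_noise = 0, n_sites = 200),
                            seed = 2)
  expect_identical(unclass(L0$covariates$elevation_m),
                   unclass(L0b$covariates$elevation_m))
  # elevation within the montane bounds
  e <- unclass(L0$covariates$elevation_m)
  expect_true(all(e >= 1800 & e <= 3000))
})

test_that("the label flip fraction matches the nominal noise rate", {
  p <- landscape_params(nrow = 150, ncol = 150, label_noise = 0.05,
                        n_sites = 10000)
  L <- simulate_landscape(p, seed = 8)
  flipped <- mean(L$sites$label != L$sites$true_regime)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(flipped - 0.05), 3 * se)
})

test_that("observed-severity simulation honors the concordance parameter", {
  reg <- fire_grid(matrix(rep(c(1L, 2L), each = 200), 20, 20), cell_m = 30)
  per <- grid_like(reg, 1)
  obs1 <- simulate_observed_fire(reg, per, concordance = 1, seed = 3)
  expect_equal(as.vector(unclass(binarize_observed(obs1))),
               as.vector(unclass(reg)))
  expect_true(all(unclass(obs1) %in% 1:4))

  # closed-form expectation of the observed-low fraction at c = 0.7
  p_low <- 0.5; conc <- 0.7
  obs <- simulate_observed_fire(reg, per, concordance = conc, seed = 5)
  frac_low <- mean(unclass(binarize_observed(obs)) == 1L)
  expected <- p_low * conc + (1 - p_low) * (1 - conc)
  expect_lt(abs(frac_low - expected), 3 * sqrt(expected * (1 - expected) / 400))

  # all-low historical perimeter reproduces the invalid-test condition
  reg_low <- grid_like(reg, 1L)
  obs_l <- simulate_observed_fire(reg_low, per, concordance = 0.5, seed = 6)
  fc <- compare_fire(obs_l, reg_low, per)
  expect_false(fc$valid)
  expect_error(simulate_observed_fire(reg, grid_like(reg, 0), 0.5, 1), "empty")
})

test_that("simulated behavior hits the target surface intensity mean", {
  reg <- fire_grid(matrix(1L, 100, 100), cell_m = 30)
  beh <- simulate_behavior(reg, seed = 11, p_crown = c(low = 0, mixed = 1))
  fi <- as.vector(unclass(beh$intensity_kwm))
  # all surface by construction; lognormal mean 14,020 with sdlog 0.5
  sdlog <- 0.5
  mu <- log(14020) - sdlog^2 / 2
  sd_mean <- sqrt((exp(sdlog^2) - 1) * exp(2 * mu + sdlog^2)) / sqrt(1e4)
  expect_lt(abs(mean(fi) - 14020), 3 * sd_mean)
  expect_true(all(unclass(beh$crown_class) == 1L))

  # crown-only versus surface-only regimes fill only two crossmap cells
  reg2 <- fire_grid(matrix(rep(c(1L, 2L), each = 50), 10, 10), cell_m = 30)
  beh2 <- simulate_behavior(reg2, seed = 12, p_crown = c(low = 0, mixed = 1))
  cm <- crossmap(reg2, beh2)
  occupied <- cm$n_cells > 0
  expect_equal(cm$historical[occupied], c("low", "mixed"))
  expect_equal(cm$behavior[occupied], c("surface", "crown_or_torch"))

  b1 <- simulate_behavior(reg2, seed = 12)
  b2 <- simulate_behavior(reg2, seed = 12)
  expect_identical(b1, b2)
})

test_that("stand extinction raises an informative error", {
  p <- regime_params("mixed", severity_mix = c(0, 0, 1),
                     canopy_mortality = list(low = c(0, 0), moderate = c(1, 1),
                                             high = c(1, 1)),
                     pulse_size = 0, background_establish_rate = 0,
                     init_cohort_size = 5, snag_persistence_yr = 0)
  expect_error(simulate_site_history(p, seed = 1), "extinction")
})
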