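mkgrid <- function(v, nr, nc, cell = 30) fire_grid(matrix(v, nr, nc), cell_m = cell)

test_that("observed classes binarize by the 1-2 / 3-4 split and idempotently", {
  g <- mkgrid(c(1L, 2L, 3L, 4L, 6L, NA), 2, 3)
  b <- binarize_observed(g)
  expect_equal(as.vector(unclass(b)),
               c(REGIME_LOW, REGIME_LOW, REGIME_MIXED, REGIME_MIXED, NA, NA))
  expect_equal(unclass(binarize_observed(b)), unclass(b))
})

test_that("the fire comparison reproduces the hand-computed chi-square", {
  # N = 100 pixels, historical p_low = 0.5, observed low = 40 -> chi2 = 4
  hist <- mkgrid(rep(c(1L, 2L), each = 50), 10, 10)
  obs <- mkgrid(c(rep(1L, 40), rep(3L, 60)), 10, 10)
  per <- mkgrid(1, 10, 10)
  fc <- compare_fire(obs, hist, per, fire_id = "toy")
  expect_equal(fc$n_pixels, 100L)
  expect_equal(fc$chi2, 4.0)
  expect_equal(fc$df, 1L)
  expect_true(fc$valid)
  expect_equal(fc$p, pchisq(4, 1, lower.tail = FALSE))

  # observed equals expected -> chi2 = 0
  obs0 <- mkgrid(c(rep(1L, 50), rep(3L, 50)), 10, 10)
  expect_equal(compare_fire(obs0, hist, per)$chi2, 0)

  # all-low historical map -> expected mixed count 0 -> invalid test
  hist_low <- mkgrid(1L, 10, 10)
  fc2 <- compare_fire(obs, hist_low, per)
  expect_false(fc2$valid)
  expect_true(is.na(fc2$chi2))
  expect_error(compare_fire(obs, hist, mkgrid(0, 10, 10)), "empty")
})

test_that("chi-square matches the generic goodness-of-fit oracle", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    p <- runif(1, 0.2, 0.8)
    hist <- mkgrid(c(rep(1L, round(n * p)), rep(2L, n - round(n * p))), 1, n)
    o_low <- sample.int(n - 1, 1)
    obs <- mkgrid(c(rep(2L, o_low), rep(4L, n - o_low)), 1, n)
    fc <- compare_fire(obs, hist, mkgrid(1, 1, n))
    e_low <- n * round(n * p) / n
    expect_equal(fc$chi2,
                 oracle_chisq(c(o_low, n - o_low), c(e_low, n - e_low)),
                 tolerance = 1e-12)
    ref <- suppressWarnings(
      chisq.test(c(o_low, n - o_low), p = c(e_low / n, 1 - e_low / n)))
    expect_equal(fc$chi2, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("severity proportions partition the perimeter", {
  obs <- mkgrid(c(rep(1L, 3), rep(2L, 2), rep(3L, 3), rep(4L, 2)), 2, 5)
  per <- mkgrid(1, 2, 5)
  pr <- fire_severity_proportions(obs, per)
  expect_equal(pr$pct, c(30, 20, 30, 20))
  expect_equal(sum(pr$pct), 100, tolerance = 0.1)
  one <- fire_severity_proportions(mkgrid(2L, 2, 5), per)
  expect_equal(one$pct, c(0, 100, 0, 0))
  expect_error(fire_severity_proportions(mkgrid(NA_integer_, 2, 5), per),
               "no classified")
})

test_that("behavior classification maps crown classes and intensity bands", {
  cc <- mkgrid(c(1L, 2L, 3L, NA), 2, 2)
  b <- classify_behavior(list(crown_class = cc))$binary
  expect_equal(as.vector(unclass(b)), c(1L, 2L, 2L, NA))

  fi <- mkgrid(c(32999, 33000, 41000, 10), 2, 2)
  bi <- classify_behavior(list(intensity_kwm = fi), mode = "intensity")
  expect_equal(as.vector(unclass(bi$binary)), c(1L, 2L, 2L, 1L))
  expect_equal(as.vector(unclass(bi$band)), c(1L, 2L, 3L, 1L))
})

test_that("the four-way crossmap partitions area and averages intensity", {
  hist <- mkgrid(c(1L, 1L, 2L, 2L), 2, 2)
  beh <- list(crown_class = mkgrid(c(1L, 3L, 1L, 3L), 2, 2),
              intensity_kwm = mkgrid(c(10, 50, 20, 60), 2, 2))
  cm <- crossmap(hist, beh)
  expect_equal(cm$pct, rep(25, 4))
  expect_equal(sum(cm$n_cells), 4L)
  expect_equal(sum(cm$pct), 100, tolerance = 0.1)
  expect_equal(cm$mean_intensity_kwm[cm$historical == "low" &
                                       cm$behavior == "surface"], 10)
  expect_equal(cm$mean_intensity_kwm[cm$historical == "mixed" &
                                       cm$behavior == "crown_or_torch"], 60)
  # merging the two historical-low categories conserves the low total
  low_total <- sum(cm$n_cells[cm$historical == "low"])
  expect_equal(low_total, sum(unclass(hist) == 1L))
})

test_that("behavior verification reproduces the worked Kruskal-Wallis value", {
  obs <- mkgrid(rep(1:3, each = 3), 3, 3)
  beh <- list(intensity_kwm = mkgrid(1:9, 3, 3),
              crown_class = mkgrid(rep(c(1L, 3L, 3L), 3), 3, 3))
  v <- verify_behavior(obs, beh, mkgrid(1, 3, 3), n_points = 9, seed = 1)
  expect_equal(v$kw_intensity$statistic, 7.2, tolerance = 1e-10)
  expect_equal(v$kw_intensity$df, 2L)
  expect_equal(v$by_class$median_intensity_kwm, c(2, 5, 8))
})

test_that("the KW statistic equals brute-force ranks, including ties", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    vals <- sample(1:6, n, replace = TRUE)       # many ties
    grp <- sample(1:3, n, replace = TRUE)
    if (length(unique(grp)) < 2 || length(unique(vals)) < 2) next
    kt <- kruskal.test(vals, factor(grp))
    expect_equal(unname(kt$statistic), oracle_kw(vals, grp), tolerance = 1e-10)
  }
})

test_that("verification is label-symmetric and degenerate-safe", {
  obs <- mkgrid(rep(1:3, each = 3), 3, 3)
  beh_const <- list(intensity_kwm = mkgrid(5, 3, 3),
                    crown_class = mkgrid(1L, 3, 3))
  v <- verify_behavior(obs, beh_const, mkgrid(1, 3, 3), n_points = 9, seed = 1)
  expect_equal(v$kw_intensity$statistic, 0)
  expect_equal(v$kw_intensity$note, "no variation in values")
  v1 <- verify_behavior(mkgrid(2L, 3, 3),
                        list(intensity_kwm = mkgrid(1:9, 3, 3),
                             crown_class = mkgrid(1L, 3, 3)),
                        mkgrid(1, 3, 3), n_points = 9, seed = 1)
  expect_true(is.na(v1$kw_intensity$statistic))

  # permuting which class id labels which group leaves H unchanged
  obs_perm <- mkgrid(rep(c(3L, 1L, 2L), each = 3), 3, 3)
  beh <- list(intensity_kwm = mkgrid(1:9, 3, 3),
              crown_class = mkgrid(1L, 3, 3))
  h1 <- verify_behavior(obs, beh, mkgrid(1, 3, 3), 9, 1)$kw_intensity$statistic
  h2 <- verify_behavior(obs_perm, beh, mkgrid(1, 3, 3), 9, 1)$kw_intensity$statistic
  expect_equal(h1, h2)
})

test_that("median intensity rises with severity class on synthetic behavior", {
  set.seed(6)
  # class-increasing intensity by construction
  cls <- mkgrid(sample(1:4, 400, replace = TRUE), 20, 20)
  fi <- grid_like(cls, unclass(cls) * 1000 + runif(400, 0, 500))
  beh <- list(intensity_kwm = fi, crown_class = grid_like(cls, 1L))
  v <- verify_behavior(cls, beh, mkgrid(1, 20, 20), n_points = 400, seed = 2)
  expect_true(all(diff(v$by_class$median_intensity_kwm) >= 0))
})
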