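test_that("fire calls match forced examples including the 80/20 boundaries", {
  mk <- trees_with_percentages
  expect_equal(classify_fire(mk(90, 10), 1800)$severity, "low")
  expect_equal(classify_fire(mk(10, 85), 1800)$severity, "high")
  expect_equal(classify_fire(mk(50, 45), 1800)$severity, "moderate")
  expect_equal(classify_fire(mk(80, 20), 1800)$severity, "low")   # inclusive
  ex <- classify_fire(mk(100, 0), 1800)
  expect_equal(ex$severity, "excluded")
  expect_equal(ex$exclusion_reason, "no_establishment_40yr")
  expect_error(classify_fire(mk(0, 0)[0, ], 1800), "no retained")
})

test_that("the percentage rubric agrees with the literal oracle on a 1% grid", {
  grid <- expand.grid(r = 0:100, e = 0:100)
  got <- severity_from_percentages(grid$r, grid$e)
  want <- mapply(oracle_severity, grid$r, grid$e)
  expect_identical(got, unname(want))
})

test_that("classify_fire agrees with the oracle on constructed tree sets", {
  set.seed(11)
  for (i in 1:200) {
    r <- sample(0:100, 1); e <- sample(0:(100 - r), 1)
    call <- classify_fire(trees_with_percentages(r, e), 1800)
    expect_equal(call$pct_remnant, r)
    expect_equal(call$pct_establish, e)
    expect_equal(call$severity, oracle_severity(r, e))
  }
})

test_that("excluded cores never change the percentage metrics", {
  trees <- trees_with_percentages(60, 30)
  with_excluded <- rbind(trees, data.frame(
    site_id = "t", tree_id = c("x1", "x2"),
    establishment_year = c(1500L, 1900L), excluded = TRUE))
  a <- classify_fire(trees, 1800)
  b <- classify_fire(with_excluded, 1800)
  expect_equal(a$pct_remnant, b$pct_remnant)
  expect_equal(a$pct_establish, b$pct_establish)
  expect_equal(a$severity, b$severity)
})

test_that("spreading fires require two trees and honor the merge window", {
  scars <- data.frame(site_id = "s1", tree_id = c("A", "B", "C"),
                      scar_year_start = c(1850L, 1850L, 1872L),
                      scar_year_end = c(1850L, 1850L, 1872L),
                      season = "unknown")
  sf <- find_spreading_fires(scars)
  expect_equal(sf$year, 1850L)
  expect_equal(sf$n_trees_scarred, 2L)

  amb <- data.frame(site_id = "s1", tree_id = c("A", "B"),
                    scar_year_start = c(1859L, 1860L),
                    scar_year_end = c(1860L, 1860L),
                    season = c("dormant", "unknown"))
  expect_equal(nrow(find_spreading_fires(amb, merge_window = 0L)), 0L)
  merged <- find_spreading_fires(amb, merge_window = 1L)
  expect_equal(merged$year, 1859L)
  expect_equal(merged$n_trees_scarred, 2L)
  expect_error(find_spreading_fires(scars, min_trees = 0L), "min_trees")
})

test_that("mean fire interval covers the arithmetic and degenerate cases", {
  expect_equal(mean_fire_interval(c(1700, 1712, 1730, 1745)), 15)
  expect_true(is.na(mean_fire_interval(1850)))
  expect_equal(mean_fire_interval(c(1700, 1730)), 30)   # not < 30
  expect_equal(mean_fire_interval(c(1700, 1712, 1712, 1730, 1745)), 15)
})

test_that("early fires without a pulse are dropped before mixed-severity fire", {
  calls <- data.frame(
    site_id = "s1", year = c(1750L, 1820L),
    pct_remnant = c(90, 10), pct_establish = c(5, 85),
    severity = c("low", "high"), exclusion_reason = NA_character_)
  out <- apply_sequence_exclusions(calls)
  expect_equal(out$severity, c("excluded", "high"))
  expect_equal(out$exclusion_reason[1], "pre_mixed_no_pulse")

  calls$pct_establish[1] <- 30
  expect_equal(apply_sequence_exclusions(calls)$severity, c("low", "high"))

  all_low <- calls; all_low$severity <- c("low", "low")
  expect_equal(apply_sequence_exclusions(all_low)$severity, c("low", "low"))
})

test_that("site regimes follow the frequency and severity evidence", {
  mkcalls <- function(sev) data.frame(
    site_id = "s1", year = seq(1700L, by = 20L, length.out = length(sev)),
    pct_remnant = 50, pct_establish = 50, severity = sev,
    exclusion_reason = NA_character_)
  expect_equal(classify_site_regime(mkcalls(rep("low", 5)), mfi = 12)$regime,
               "low_only")
  expect_equal(classify_site_regime(mkcalls(c("low", "moderate")), mfi = 40)$regime,
               "mixed_no_high")
  expect_equal(classify_site_regime(mkcalls(c("low", "high")), mfi = 12)$regime,
               "mixed_with_high")
  # frequent-fire criterion fails: all-low calls but long intervals
  expect_equal(classify_site_regime(mkcalls(rep("low", 3)), mfi = 45)$regime,
               "mixed_no_high")
  expect_equal(classify_site_regime(mkcalls(rep("low", 3)), mfi = NA)$regime,
               "mixed_no_high")
  expect_error(classify_site_regime(mkcalls("excluded"), mfi = 12),
               "unclassifiable")
})

test_that("composite chronology counts recorder and recording sites", {
  scars <- rbind(
    data.frame(site_id = "s1", tree_id = c("a", "b", "a", "b"),
               scar_year_start = c(1800L, 1800L, 1810L, 1810L)),
    data.frame(site_id = "s2", tree_id = c("c", "d"),
               scar_year_start = c(1805L, 1810L)),
    data.frame(site_id = "s3", tree_id = "e", scar_year_start = 1802L)
  )
  ch <- recorder_sites_by_year(scars)
  # 1810: s1 has two recorder trees and a spreading fire; s2 reaches two
  # recorder trees in 1810 but only one tree scarred that year
  row1810 <- ch[ch$year == 1810, ]
  expect_equal(row1810$n_recorder_sites, 2L)
  expect_equal(row1810$n_sites_recording, 1L)
  expect_equal(row1810$pct_recording, 50)
  # before any site has two scarred trees there are no recorder sites
  expect_true(all(ch$n_sites_recording <= ch$n_recorder_sites))
  # a site with no scars never changes the counts
  ch2 <- recorder_sites_by_year(rbind(scars[0, ], scars))
  expect_identical(ch, ch2)
})

test_that("widespread fire years use the four-site threshold", {
  ch <- data.frame(year = 1800:1803, n_recorder_sites = 10,
                   n_sites_recording = c(4L, 3L, 7L, 0L),
                   pct_recording = c(40, 30, 70, 0))
  expect_equal(widespread_fire_years(ch), c(1800L, 1802L))
  expect_length(widespread_fire_years(ch[0, ]), 0L)
})

test_that("establishment histograms count, normalize and translate", {
  h <- establishment_histogram(c(1821, 1830, 1841), origin = 1820)
  expect_equal(h$proportion, c(2 / 3, 1 / 3))
  expect_equal(h$bin_start, c(1820L, 1840L))
  h1 <- establishment_histogram(1850)
  expect_equal(h1$proportion, 1)
  # translation equivariance: +20 years shifts bins by exactly one
  set.seed(3)
  yrs <- sample(1700:1900, 40, replace = TRUE)
  a <- establishment_histogram(yrs, origin = 1700)
  b <- establishment_histogram(yrs + 20, origin = 1700)
  expect_equal(b$bin_start, a$bin_start + 20L)
  expect_equal(b$proportion, a$proportion)
  # per-group proportions always sum to one
  g <- establishment_histogram(yrs, group = rep(c("x", "y"), 20))
  expect_equal(as.vector(tapply(g$proportion, g$group, sum)),
               c(1, 1), tolerance = 1e-9)
  expect_warning(establishment_histogram(NA_integer_), "empty")
})

test_that("composite counts are invariant to site ordering", {
  set.seed(5)
  scars <- data.frame(
    site_id = sample(paste0("s", 1:6), 120, replace = TRUE),
    tree_id = sample(paste0("t", 1:40), 120, replace = TRUE),
    scar_year_start = sample(1750:1850, 120, replace = TRUE))
  scars <- scars[!duplicated(scars[c("site_id", "tree_id", "scar_year_start")]), ]
  a <- recorder_sites_by_year(scars)
  b <- recorder_sites_by_year(scars[sample(nrow(scars)), ])
  expect_identical(a, b)
})
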