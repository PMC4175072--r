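test_that("a separable one-covariate problem yields one split and PCC 100", {
  x <- data.frame(v = c(1:10, 21:30))
  y <- rep(c("low", "mixed"), each = 10)
  ft <- fit_cart(x, y, folds = 5, seed = 1)
  expect_equal(ft$pruned_size, 2L)
  expect_equal(ft$root$var, "v")
  expect_gt(ft$root$threshold, 10)
  expect_lte(ft$root$threshold, 21)
  expect_equal(ft$pcc, 100)
  expect_equal(as.character(predict(ft, data.frame(v = c(5, 25)))),
               c("low", "mixed"))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_cart(data.frame(v = rep(1, 20)),
                        rep(c("a", "b"), 10), seed = 1),
               "degenerate|no valid split")
  expect_error(fit_cart(data.frame(v = 1:10), rep("a", 10), seed = 1),
               "two classes")
  expect_error(fit_cart(data.frame(v = c(NA, 1:19)),
                        rep(c("a", "b"), 10), seed = 1), "complete")
})

test_that("the selected root split equals the exhaustive Gini oracle", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(c(60, 120, 300), 1)
    x <- data.frame(a = runif(n, 0, 100), b = rnorm(n), c = runif(n))
    y <- ifelse(x$a + 5 * x$b + rnorm(n, 0, 8) > 50, "mixed", "low")
    if (length(unique(y)) < 2 || min(table(y)) < 10) next
    ft <- fit_cart(x, y, seed = i)
    orc <- oracle_gini_split(x, y)
    expect_equal(ft$full$var, orc$var)
    expect_equal(ft$full$threshold, orc$threshold, tolerance = 1e-10)
  }
})

test_that("deeper splits also match the oracle applied to each node's data", {
  set.seed(9)
  n <- 400
  x <- data.frame(a = runif(n, 0, 100), b = runif(n, 0, 100))
  y <- ifelse(x$a <= 40 | x$b <= 20, "low", "mixed")
  flip <- runif(n) < 0.03
  y[flip] <- ifelse(y[flip] == "low", "mixed", "low")
  ft <- fit_cart(x, y, seed = 2)
  check_node <- function(node, xx, yy) {
    if (node$is_leaf) return(invisible(NULL))
    orc <- oracle_gini_split(xx, yy)
    expect_equal(node$var, orc$var)
    expect_equal(node$threshold, orc$threshold, tolerance = 1e-10)
    left <- xx[[node$var]] <= node$threshold
    check_node(node$left, xx[left, , drop = FALSE], yy[left])
    check_node(node$right, xx[!left, , drop = FALSE], yy[!left])
  }
  check_node(ft$full, x, y)
})

test_that("fold assignment is deterministic given the seed", {
  set.seed(123)
  x <- data.frame(a = runif(100), b = runif(100))
  y <- ifelse(x$a > 0.5, "mixed", "low")
  f1 <- fit_cart(x, y, seed = 42)
  f2 <- fit_cart(x, y, seed = 42)
  expect_identical(f1$cv_sizes, f2$cv_sizes)
  expect_identical(f1$root, f2$root)
})

test_that("PCC and AUC match worked values and brute-force rank computation", {
  pred <- c(rep("a", 187), rep("b", 45))
  lab <- rep("a", 232)
  expect_equal(round(evaluate_model(pred, lab)$pcc, 1), 80.6)

  scores <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  labs <- c("n", "n", "n", "p", "p")
  expect_equal(evaluate_model(labs, labs, scores)$auc, 1.0)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    sc <- sample(1:8, n, replace = TRUE)   # heavy ties
    lb <- sample(c("n", "p"), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(lb)) < 2) next
    expect_equal(evaluate_model(lb, lb, sc)$auc, oracle_auc(sc, lb),
                 tolerance = 1e-12)
  }
  # labels independent of scores -> AUC near 0.5
  set.seed(8)
  sc <- runif(5000); lb <- sample(c("n", "p"), 5000, replace = TRUE)
  expect_lt(abs(evaluate_model(lb, lb, sc)$auc - 0.5), 0.03)
  expect_error(evaluate_model(character(), character()), "empty")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  sc <- c(rnorm(40), rnorm(60, 1))
  lb <- rep(c("n", "p"), c(40, 60))
  ours <- evaluate_model(lb, lb, sc)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<", levels = c("n", "p"))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("the mapped rule is inclusive at both thresholds and pointwise", {
  elev <- fire_grid(matrix(c(2263, 2300, 2300, 2200), 2, 2), cell_m = 30)
  slope <- fire_grid(matrix(c(35, 4, 5, 10), 2, 2), cell_m = 30)
  reg <- apply_rule(list(elevation_m = elev, slope_deg = slope))
  expect_equal(as.vector(unclass(reg)),
               c(REGIME_LOW, REGIME_LOW, REGIME_MIXED, REGIME_LOW))
  # idempotent via determinism, nodata preserved
  elev2 <- elev; elev2[1, 1] <- NA
  reg2 <- apply_rule(list(elevation_m = elev2, slope_deg = slope))
  expect_true(is.na(unclass(reg2)[1, 1]))
  expect_error(apply_rule(list(elevation_m = elev)), "slope_deg")
})

test_that("area summaries count cells, hectares and percentages", {
  reg <- fire_grid(matrix(c(1L, 1L, 1L, 2L), 2, 2), cell_m = 30)
  s <- summarize_area(reg)
  expect_equal(s$pct[s$regime == "low"], 75)
  expect_equal(s$area_ha[s$regime == "low"], 3 * 0.09)
  expect_equal(sum(s$pct), 100, tolerance = 0.1)

  cover <- fire_grid(matrix(c(1L, 1L, 2L, 2L), 2, 2), cell_m = 30)
  sc <- summarize_area(reg, cover, cover_levels = c("ponderosa", "mixed_conifer"))
  for (cv in unique(sc$cover))
    expect_equal(sum(sc$pct[sc$cover == cv]), 100, tolerance = 0.1)

  # permuting cells leaves the overall table unchanged
  set.seed(2)
  v <- sample(c(1L, 2L), 36, replace = TRUE)
  g1 <- fire_grid(matrix(v, 6, 6), cell_m = 30)
  g2 <- fire_grid(matrix(sample(v), 6, 6), cell_m = 30)
  expect_equal(summarize_area(g1), summarize_area(g2))

  expect_warning(s0 <- summarize_area(fire_grid(matrix(NA_integer_, 2, 2))),
                 "no classified")
  expect_equal(nrow(s0), 0L)
})

test_that("the landscape rule is recovered from noisy synthetic sites", {
  L <- simulate_landscape(landscape_params(), seed = 5)
  x <- L$sites[, c("elevation_m", "slope_deg", "aspect_sin",
                   "aspect_arcsine", "curvature")]
  ft <- fit_cart(x, L$sites$label, seed = 5)
  expect_equal(ft$root$var, "elevation_m")
  expect_lt(abs(ft$root$threshold - 2263), 50)
  orc <- oracle_gini_split(x, L$sites$label)
  expect_equal(ft$full$var, orc$var)
  expect_equal(ft$full$threshold, orc$threshold, tolerance = 1e-10)
})

test_that("bagged variable importance ranks the generating variables first", {
  set.seed(4)
  n <- 300
  x <- data.frame(a = runif(n), b = runif(n), noise = runif(n))
  y <- ifelse(x$a > 0.5, "mixed", "low")
  imp <- cart_variable_importance(x, y, n_trees = 30, seed = 4)
  expect_equal(names(imp)[1], "a")
  expect_gt(imp["a"], imp["noise"])
})
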