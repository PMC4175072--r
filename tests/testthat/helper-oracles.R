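# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths.

# Literal transcription of the severity rubric: no-establishment exclusion,
# then high (<20 survived and >80 established), then low (>=80 and <=20),
# moderate as the residual.
oracle_severity <- function(pct_remnant, pct_establish) {
  if (pct_establish == 0) return("excluded")
  if (pct_remnant < 20 && pct_establish > 80) return("high")
  if (pct_remnant >= 80 && pct_establish <= 20) return("low")
  "moderate"
}

# Circumradius of the circle through the three arc points
# (0, 0), (L, 0), (L/2, h): R = abc / (4K).
oracle_arc_radius <- function(chord, arc_height) {
  p1 <- c(0, 0); p2 <- c(chord, 0); p3 <- c(chord / 2, arc_height)
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  K <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
             (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
  a * b * cc / (4 * K)
}

# Exhaustive Gini split search: independent double loop over variables and
# midpoint thresholds, strictly-greater-decrease tie-break in column order.
oracle_gini_split <- function(x, y, min_leaf = 5L) {
  y <- as.integer(factor(y))
  gini <- function(v) {
    if (!length(v)) return(0)
    p <- table(factor(v, levels = 1:2)) / length(v)
    1 - sum(p^2)
  }
  n <- length(y)
  parent <- gini(y) * n
  best <- NULL
  for (var in names(x)) {
    v <- x[[var]]
    if (!is.numeric(v)) next
    cand <- sort(unique(v))
    if (length(cand) < 2) next
    thrs <- (cand[-1] + cand[-length(cand)]) / 2
    for (thr in thrs) {
      left <- v <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      dec <- parent - gini(y[left]) * sum(left) - gini(y[!left]) * sum(!left)
      if (is.null(best) || dec > best$decrease + 1e-12)
        best <- list(var = var, threshold = thr, decrease = dec)
    }
  }
  best
}

# Kruskal-Wallis H by direct rank computation with tie correction.
oracle_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ssq <- tapply(r, groups, function(ri) sum(ri)^2 / length(ri))
  H <- 12 / (N * (N + 1)) * sum(ssq) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# AUC as the Mann-Whitney pairwise comparison probability.
oracle_auc <- function(scores, labels) {
  labf <- as.integer(factor(labels))
  sp <- scores[labf == 2]; sn <- scores[labf == 1]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Chi-square goodness of fit, generic k-cell formula.
oracle_chisq <- function(observed, expected) sum((observed - expected)^2 / expected)

# Unweighted least-squares plane fit over one 3x3 window; returns the slope
# (degrees) of the fitted plane.
oracle_plane_slope <- function(win, cell) {
  xy <- expand.grid(dx = -1:1, dy = -1:1) * cell
  z <- as.vector(t(win[3:1, ]))   # match row 1 = north to increasing dy
  co <- coef(lm(z ~ xy$dx + xy$dy))
  atan(sqrt(co[2]^2 + co[3]^2)) * 180 / pi
}

# Toy tree table realizing exact remnant/establishment percentages at N=100.
trees_with_percentages <- function(pct_remnant, pct_establish, fire_year = 1800,
                                   window = 40) {
  k <- pct_remnant; m <- pct_establish
  stopifnot(k + m <= 100, k == round(k), m == round(m))
  est <- c(rep(fire_year - 10, k), rep(fire_year + 5, m),
           rep(fire_year + window + 50, 100 - k - m))
  data.frame(site_id = "t", tree_id = sprintf("t%03d", 1:100),
             establishment_year = est, excluded = FALSE,
             stringsAsFactors = FALSE)
}

# Random valid fhx record sets for round-trip property tests.
random_fhx_records <- function(seed) {
  set.seed(seed)
  n_series <- sample(1:6, 1)
  series <- data.frame(
    tree_id = sprintf("TR%02d", seq_len(n_series)),
    first_year = sample(1600:1700, n_series, replace = TRUE),
    stringsAsFactors = FALSE
  )
  series$last_year <- series$first_year + sample(50:200, n_series, replace = TRUE)
  scars <- do.call(rbind, lapply(seq_len(n_series), function(j) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    yrs <- sort(sample(series$first_year[j]:series$last_year[j], k))
    data.frame(tree_id = series$tree_id[j], scar_year_start = yrs,
               scar_year_end = yrs,
               season = sample(c("dormant", "unknown"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(scars))
    scars <- data.frame(tree_id = character(), scar_year_start = integer(),
                        scar_year_end = integer(), season = character(),
                        stringsAsFactors = FALSE)
  list(series = series, scars = scars)
}
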