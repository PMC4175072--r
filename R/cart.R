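#' Binary classification tree with cross-validated size pruning
#'
#' Grows a CART-style binary tree by exhaustive Gini-impurity split search
#' (every midpoint between distinct sorted values of each numeric covariate;
#' one-level-versus-rest splits for factors), then selects the tree size by
#' 10-fold cross-validation: each fold records the pruned subtree size with
#' the smallest held-out misclassification, and the full tree is pruned to
#' the rounded mean of the per-fold best sizes by weakest-link
#' (cost-complexity) collapsing.  Fold assignment is deterministic given
#' `seed`.
#'
#' Class priors default to the observed class frequencies; `priors =
#' "balanced"` reweights observations so both classes carry equal total
#' weight (useful for strongly imbalanced site sets).
#'
#' @param x data frame of covariates (numeric and/or factor columns).
#' @param y two-class response (character or factor).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param min_leaf minimum observations per leaf (default 5).
#' @param max_depth maximum tree depth (default 12).
#' @param priors `"proportional"` (default) or `"balanced"`.
#' @return object of class `fitted_tree`: the pruned `root` node, the full
#'   grown tree, `cv_sizes` (best size per fold), `pruned_size`,
#'   `grown_size`, in-sample `pcc` and `auc`, and the class `levels`.
#' @seealso [predict.fitted_tree()], [evaluate_model()]
#' @export
fit_cart <- function(x, y, folds = 10L, seed = 1L, min_leaf = 5L,
                     max_depth = 12L, priors = c("proportional", "balanced")) {
  priors <- match.arg(priors)
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("fit_cart requires exactly two classes; got ",
         paste(levels(y), collapse = ", "))
  if (any(table(y) < 2L)) stop("need at least 2 observations per class")
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x)) stop("covariates must be complete (no NA) for every site")
  w <- rep(1, length(y))
  if (priors == "balanced") w <- 0.5 * length(y) / table(y)[as.integer(y)]

  full <- grow_tree(x, as.integer(y), w, min_leaf = min_leaf,
                    max_depth = max_depth)
  grown_size <- n_leaves(full)
  if (grown_size < 2L)
    stop("no valid split found (degenerate stump): covariates carry no signal")

  set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), length(y)))
  cv_sizes <- integer(folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (length(unique(y[tr])) < 2L) { cv_sizes[k] <- 1L; next }
    tree_k <- grow_tree(x[tr, , drop = FALSE], as.integer(y[tr]), w[tr],
                        min_leaf = min_leaf, max_depth = max_depth)
    sizes <- seq_len(n_leaves(tree_k))
    err <- vapply(sizes, function(s) {
      pk <- predict_tree(prune_to_size(tree_k, s), x[!tr, , drop = FALSE])
      mean(pk$class != as.integer(y[!tr]))
    }, numeric(1L))
    cv_sizes[k] <- sizes[which.min(err)]   # ties -> smallest size
  }
  target <- max(1L, as.integer(round(mean(cv_sizes))))
  pruned <- prune_to_size(full, target)

  pr <- predict_tree(pruned, x)
  ev <- evaluate_model(levels(y)[pr$class], y, scores = pr$score)
  structure(list(root = pruned, full = full, cv_sizes = cv_sizes,
                 pruned_size = n_leaves(pruned), grown_size = grown_size,
                 pcc = ev$pcc, auc = ev$auc, levels = levels(y)),
            class = "fitted_tree")
}

#' @export
print.fitted_tree <- function(x, ...) {
  cat(sprintf("<fitted_tree> %d leaves (grown %d), PCC %.1f%%, AUC %.3f\n",
              x$pruned_size, x$grown_size, x$pcc, x$auc))
  if (!x$root$is_leaf)
    cat(sprintf("  root split: %s %s %s\n", x$root$var,
                if (is.null(x$root$level)) "<=" else "==",
                if (is.null(x$root$level)) format(x$root$threshold) else x$root$level))
  invisible(x)
}

#' @export
predict.fitted_tree <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  pr <- predict_tree(object$root, newdata)
  if (type == "class") factor(object$levels[pr$class], levels = object$levels)
  else pr$score
}

# ---- internal tree machinery ------------------------------------------------

gini_impurity <- function(w1, w2) {
  n <- w1 + w2
  ifelse(n > 0, 1 - (w1 / n)^2 - (w2 / n)^2, 0)
}

# Exhaustive best split of one node.  y in {1, 2}; w observation weights.
# Returns NULL or list(var, threshold|level, decrease, left_idx logical).
best_split <- function(x, y, w, min_leaf) {
  n <- length(y)
  w1_tot <- sum(w[y == 1L]); w2_tot <- sum(w[y == 2L])
  parent <- gini_impurity(w1_tot, w2_tot) * (w1_tot + w2_tot)
  best <- NULL
  for (var in names(x)) {
    v <- x[[var]]
    if (is.numeric(v)) {
      o <- order(v)
      vs <- v[o]; ys <- y[o]; ws <- w[o]
      cw1 <- cumsum(ws * (ys == 1L)); cw2 <- cumsum(ws * (ys == 2L))
      cand <- which(diff(vs) > 0)
      cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
      if (!length(cand)) next
      lw1 <- cw1[cand]; lw2 <- cw2[cand]
      child <- gini_impurity(lw1, lw2) * (lw1 + lw2) +
        gini_impurity(w1_tot - lw1, w2_tot - lw2) * (w1_tot + w2_tot - lw1 - lw2)
      dec <- parent - child
      j <- which.max(dec)
      if (is.null(best) || dec[j] > best$decrease + 1e-12) {
        thr <- (vs[cand[j]] + vs[cand[j] + 1L]) / 2
        best <- list(var = var, threshold = thr, level = NULL,
                     decrease = dec[j], left_idx = v <= thr)
      }
    } else {
      lev <- unique(as.character(v))
      if (length(lev) < 2L) next
      for (l in lev) {
        left <- as.character(v) == l
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        lw1 <- sum(w[left & y == 1L]); lw2 <- sum(w[left & y == 2L])
        child <- gini_impurity(lw1, lw2) * (lw1 + lw2) +
          gini_impurity(w1_tot - lw1, w2_tot - lw2) *
          (w1_tot + w2_tot - lw1 - lw2)
        dec <- parent - child
        if (is.null(best) || dec > best$decrease + 1e-12)
          best <- list(var = var, threshold = NULL, level = l,
                       decrease = dec, left_idx = left)
      }
    }
  }
  best
}

grow_tree <- function(x, y, w, min_leaf = 5L, max_depth = 12L, depth = 0L) {
  w1 <- sum(w[y == 1L]); w2 <- sum(w[y == 2L])
  cls <- if (w2 > w1) 2L else 1L
  node <- list(is_leaf = TRUE, class = cls,
               score = w2 / (w1 + w2), n = length(y),
               r_leaf = min(w1, w2))   # weighted training misclassification
  if (length(unique(y)) < 2L || length(y) < 2L * min_leaf ||
      depth >= max_depth)
    return(node)
  sp <- best_split(x, y, w, min_leaf)
  if (is.null(sp) || sp$decrease <= 1e-12) return(node)
  li <- sp$left_idx
  node$is_leaf <- FALSE
  node$var <- sp$var; node$threshold <- sp$threshold; node$level <- sp$level
  node$left <- grow_tree(x[li, , drop = FALSE], y[li], w[li],
                         min_leaf, max_depth, depth + 1L)
  node$right <- grow_tree(x[!li, , drop = FALSE], y[!li], w[!li],
                          min_leaf, max_depth, depth + 1L)
  node
}

n_leaves <- function(node) {
  if (node$is_leaf) 1L else n_leaves(node$left) + n_leaves(node$right)
}

subtree_risk <- function(node) {
  if (node$is_leaf) node$r_leaf
  else subtree_risk(node$left) + subtree_risk(node$right)
}

# Weakest-link pruning: repeatedly collapse the internal node with the
# smallest per-leaf increase in training risk until at most `size` leaves.
prune_to_size <- function(node, size) {
  while (n_leaves(node) > size) {
    g <- weakest_link(node)
    node <- collapse_at(node, g$path)
  }
  node
}

weakest_link <- function(node, path = integer()) {
  if (node$is_leaf) return(NULL)
  g_here <- (node$r_leaf - subtree_risk(node)) / (n_leaves(node) - 1L)
  best <- list(g = g_here, path = path)
  for (side in 1:2) {
    child <- if (side == 1L) node$left else node$right
    cand <- weakest_link(child, c(path, side))
    if (!is.null(cand) && cand$g <= best$g) best <- cand
  }
  best
}

collapse_at <- function(node, path) {
  if (length(path) == 0L)
    return(list(is_leaf = TRUE, class = node$class, score = node$score,
                n = node$n, r_leaf = node$r_leaf))
  if (path[1L] == 1L) node$left <- collapse_at(node$left, path[-1L])
  else node$right <- collapse_at(node$right, path[-1L])
  node
}

predict_tree <- function(node, x) {
  n <- nrow(x)
  cls <- integer(n); score <- numeric(n)
  recurse <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (node$is_leaf) {
      cls[idx] <<- node$class
      score[idx] <<- node$score
      return(invisible(NULL))
    }
    v <- x[[node$var]][idx]
    left <- if (is.null(node$level)) v <= node$threshold
            else as.character(v) == node$level
    left[is.na(left)] <- FALSE
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(node, seq_len(n))
  list(class = cls, score = score)
}

#' Classification accuracy and AUC
#'
#' PCC is the overall percentage correctly classified.  AUC is computed from
#' the rank statistic (Mann-Whitney U with midranks for ties) of the scores
#' of the second class level against the first.
#'
#' @param predictions predicted class labels.
#' @param labels true class labels (two classes).
#' @param scores optional numeric scores increasing with the probability of
#'   the second class level; AUC is `NA` when absent.
#' @return list with `pcc` (percent) and `auc`.
#' @examples
#' evaluate_model(rep("a", 232), c(rep("a", 187), rep("b", 45)))$pcc  # 80.6
#' @export
evaluate_model <- function(predictions, labels, scores = NULL) {
  if (length(labels) == 0L) stop("empty input")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  pcc <- 100 * mean(as.character(predictions) == as.character(labels))
  auc <- NA_real_
  if (!is.null(scores)) {
    labf <- factor(labels)
    if (nlevels(labf) != 2L) stop("AUC requires exactly two classes")
    pos <- as.integer(labf) == 2L
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 > 0L && n0 > 0L) {
      r <- rank(scores)          # midranks for ties
      auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(pcc = pcc, auc = auc)
}

#' Bagged variable importance (exploratory)
#'
#' Grows `n_trees` trees on bootstrap resamples and accumulates each
#' variable's total Gini impurity decrease.  This is an exploratory
#' complement to the single pruned tree, not part of the mapped product.
#'
#' @inheritParams fit_cart
#' @param n_trees number of bootstrap trees.
#' @return named numeric vector of mean per-tree impurity decrease, sorted.
#' @export
cart_variable_importance <- function(x, y, n_trees = 100L, seed = 1L,
                                     min_leaf = 5L, max_depth = 6L) {
  y <- factor(y)
  set.seed(as.integer(seed))
  imp <- setNames(numeric(ncol(x)), names(x))
  for (b in seq_len(n_trees)) {
    idx <- sample.int(length(y), replace = TRUE)
    if (length(unique(y[idx])) < 2L) next
    tree_b <- grow_tree(x[idx, , drop = FALSE], as.integer(y[idx]),
                        rep(1, length(idx)), min_leaf = min_leaf,
                        max_depth = max_depth)
    acc <- function(node) {
      if (node$is_leaf) return(invisible(NULL))
      dec <- node$r_leaf - (node$left$r_leaf + node$right$r_leaf)
      imp[node$var] <<- imp[node$var] + max(dec, 0)
      acc(node$left); acc(node$right)
    }
    acc(tree_b)
  }
  sort(imp / n_trees, decreasing = TRUE)
}

#' Elevation/slope regime rule
#'
#' The two-split decision rule delineating the historical low-severity
#' regime: a cell is low severity when its elevation is at or below
#' `elev_threshold_m` (default 2263 m) or its slope is at or below
#' `slope_threshold_deg` (default 4 degrees); otherwise mixed severity.
#'
#' @param elev_threshold_m elevation threshold in meters.
#' @param slope_threshold_deg slope threshold in degrees.
#' @export
regime_rule <- function(elev_threshold_m = 2263, slope_threshold_deg = 4) {
  if (!is.finite(elev_threshold_m) || !is.finite(slope_threshold_deg))
    stop("rule thresholds must be finite")
  structure(list(elev_threshold_m = elev_threshold_m,
                 slope_threshold_deg = slope_threshold_deg),
            class = "regime_rule")
}

#' @export
print.regime_rule <- function(x, ...) {
  cat(sprintf("<regime_rule> low iff elevation <= %g m OR slope <= %g deg\n",
              x$elev_threshold_m, x$slope_threshold_deg))
  invisible(x)
}

#' Regime raster codes
#'
#' Regime rasters are integer grids: 1 = low-severity regime, 2 = mixed.
#' @export
REGIME_LOW <- 1L
#' @rdname REGIME_LOW
#' @export
REGIME_MIXED <- 2L

#' Map the regime rule across a covariate grid
#'
#' Pointwise and idempotent: each cell's class depends only on that cell's
#' elevation and slope; nodata cells stay nodata.
#'
#' @param covariates named list of aligned `fire_grid`s containing at least
#'   `elevation_m` and `slope_deg`.
#' @param rule a [regime_rule()].
#' @return integer `fire_grid` of regime codes (1 low, 2 mixed).
#' @export
apply_rule <- function(covariates, rule = regime_rule()) {
  for (band in c("elevation_m", "slope_deg"))
    if (is.null(covariates[[band]]))
      stop("covariate stack is missing the '", band, "' band")
  elev <- covariates$elevation_m; slope <- covariates$slope_deg
  check_aligned(elev, slope)
  low <- unclass(elev) <= rule$elev_threshold_m |
    unclass(slope) <= rule$slope_threshold_deg
  out <- ifelse(low, REGIME_LOW, REGIME_MIXED)
  out[is.na(unclass(elev)) | is.na(unclass(slope))] <- NA_integer_
  grid_like(elev, out)
}

#' Area summary of a regime raster
#'
#' Cell counts, hectares and percentages per regime class, overall and (when
#' a cover-type raster is supplied) per cover type.  Percentages are within
#' each cover row and sum to 100 over the regime classes.
#'
#' @param regime integer `fire_grid` of regime codes.
#' @param cover optional aligned categorical grid (integer codes or
#'   character); `cover_levels` maps integer codes to names.
#' @param cover_levels optional character vector naming integer cover codes.
#' @return data frame: `cover`, `regime`, `n_cells`, `area_ha`, `pct`.
#' @export
summarize_area <- function(regime, cover = NULL, cover_levels = NULL) {
  stopifnot(is_fire_grid(regime))
  vals <- as.vector(unclass(regime))
  cov <- if (is.null(cover)) rep("all", length(vals)) else {
    check_aligned(regime, cover)
    cv <- as.vector(unclass(cover))
    if (!is.null(cover_levels)) cover_levels[cv] else as.character(cv)
  }
  ok <- !is.na(vals) & !is.na(cov)
  if (!any(ok)) {
    warning("no classified cells")
    return(data.frame(cover = character(), regime = character(),
                      n_cells = integer(), area_ha = numeric(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  area1 <- cell_area_ha(regime)
  regname <- rep(NA_character_, length(vals))
  regname[!is.na(vals)] <- c("low", "mixed")[vals[!is.na(vals)]]
  loop_covers <- if (is.null(cover)) "all" else c("all", sort(unique(cov[ok])))
  rows <- list()
  for (cv in loop_covers) {
    sel <- if (cv == "all") ok else ok & cov == cv
    tot <- sum(sel)
    for (rg in c("low", "mixed")) {
      n <- sum(sel & regname == rg, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        cover = cv, regime = rg, n_cells = n, area_ha = n * area1,
        pct = 100 * n / tot, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
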