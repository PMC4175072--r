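# Terrain derivatives and distance surfaces for the covariate stack.

shift_mat <- function(m, dr, dc) {
  # shift matrix by (dr, dc) with NA fill; dr > 0 moves values south (down)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rfrom <- rs - dr; cfrom <- cs - dc
  rok <- rfrom >= 1 & rfrom <= nrow(m); cok <- cfrom >= 1 & cfrom <= ncol(m)
  out[rs[rok], cs[cok]] <- m[rfrom[rok], cfrom[cok]]
  out
}

#' Terrain covariates from an elevation grid
#'
#' Slope and aspect by Horn's 3x3 weighted finite differences; plan-free
#' general curvature from the Zevenbergen-Thorne quadratic surface fit,
#' reported per 100 m (positive = convex).  Aspect is the downslope azimuth
#' in degrees clockwise from north (`NA` on flat cells), with two transforms
#' for modeling: `aspect_sin` = sin(aspect) and `aspect_arcsine` =
#' asin(sqrt((1 + cos(aspect)) / 2)), the arcsine of a linearized northness
#' in \[0, 1\] (a variance-stabilizing transform; 0 = due south, pi/2 = due
#' north).  Border cells are `NA` in all derived bands.
#'
#' @param elevation a `fire_grid` of elevations in meters.
#' @return named list of aligned `fire_grid`s: `slope_deg`, `aspect_deg`,
#'   `aspect_sin`, `aspect_arcsine`, `curvature`.
#' @export
derive_terrain <- function(elevation) {
  stopifnot(is_fire_grid(elevation))
  L <- cell_size(elevation)
  if (L <= 0) stop("cell size must be positive")
  m <- unclass(elevation)
  # 3x3 neighbors: letters laid out a b c / d e f / g h i, row 1 = north
  a <- shift_mat(m,  1,  1); b <- shift_mat(m, 1, 0); c_ <- shift_mat(m, 1, -1)
  d <- shift_mat(m,  0,  1);                          f <- shift_mat(m, 0, -1)
  g <- shift_mat(m, -1,  1); h <- shift_mat(m, -1, 0); i <- shift_mat(m, -1, -1)

  dzdx <- ((c_ + 2 * f + i) - (a + 2 * d + g)) / (8 * L)           # east
  dzdy <- ((a + 2 * b + c_) - (g + 2 * h + i)) / (8 * L)           # north
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  flat <- !is.na(slope) & slope == 0
  aspect_rad <- atan2(-dzdx, -dzdy)            # azimuth of steepest descent
  aspect <- (aspect_rad * 180 / pi) %% 360
  aspect[flat] <- NA_real_

  # Zevenbergen-Thorne quadratic coefficients on the 3x3 window
  Dq <- ((d + f) / 2 - m) / L^2
  Eq <- ((b + h) / 2 - m) / L^2
  curv <- -2 * (Dq + Eq) * 100

  northness <- (1 + cos(aspect * pi / 180)) / 2
  out <- list(
    slope_deg = slope,
    aspect_deg = aspect,
    aspect_sin = sin(aspect * pi / 180),
    aspect_arcsine = asin(sqrt(pmin(pmax(northness, 0), 1))),
    curvature = curv
  )
  lapply(out, function(v) {
    v[is.na(m)] <- NA_real_
    grid_like(elevation, v)
  })
}

#' Label 8-connected components of a binary mask
#'
#' @param mask logical or 0/1 matrix (or `fire_grid`).
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- unclass(mask)
  feat <- !is.na(m) & m != 0
  lab <- matrix(0L, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  nbr_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  for (start in which(feat & lab == 0L)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      idx <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      rr <- r + nbr_dr; ccc <- cc + nbr_dc
      ok <- rr >= 1L & rr <= nr & ccc >= 1L & ccc <= nc
      nidx <- (ccc[ok] - 1L) * nr + rr[ok]
      nidx <- nidx[feat[nidx] & lab[nidx] == 0L]
      if (length(nidx)) {
        lab[nidx] <- current
        queue <- c(queue, nidx)
      }
    }
  }
  lab
}

#' Euclidean distance to the nearest feature cell
#'
#' Connected components of the feature mask smaller than `min_area_ha`
#' (8-connectivity) are removed before the distance computation, so that
#' isolated speckle (e.g. a single 900 m2 cell against a 0.1 ha minimum
#' grassland patch size) does not act as a feature edge.  Distances are
#' between cell centers, in meters; feature cells are at distance 0.
#'
#' @param mask `fire_grid` (or matrix) with nonzero/TRUE feature cells.
#' @param min_area_ha minimum retained patch area in hectares (default 0.1).
#' @param cell_m cell size; taken from the grid when `mask` is a `fire_grid`.
#' @return `fire_grid` of distances (all `Inf`, with a warning, when no
#'   feature survives the area filter).
#' @export
distance_to_feature <- function(mask, min_area_ha = 0.1,
                                cell_m = if (is_fire_grid(mask)) cell_size(mask) else 30) {
  m <- unclass(mask)
  lab <- label_components(m)
  cell_ha <- cell_m^2 / 1e4
  keep <- which(tabulate(lab[lab > 0L]) * cell_ha >= min_area_ha)
  feat <- lab %in% keep & lab > 0L
  dim(feat) <- dim(m)
  out <- matrix(Inf, nrow(m), ncol(m))
  if (!any(feat)) {
    warning("no feature patches of at least ", min_area_ha,
            " ha; all distances are Inf")
  } else {
    fi <- which(feat, arr.ind = TRUE)
    nr <- nrow(m)
    all_r <- ((seq_along(m) - 1L) %% nr) + 1L
    all_c <- ((seq_along(m) - 1L) %/% nr) + 1L
    # chunked nearest-feature scan keeps the distance matrix small
    chunk <- max(1L, floor(2e6 / nrow(fi)))
    for (s in seq(1L, length(m), by = chunk)) {
      ix <- s:min(s + chunk - 1L, length(m))
      d2 <- outer(all_r[ix], fi[, 1L], "-")^2 + outer(all_c[ix], fi[, 2L], "-")^2
      out[ix] <- sqrt(.rowMins(d2)) * cell_m
    }
  }
  if (is_fire_grid(mask)) grid_like(mask, out)
  else fire_grid(out, cell_m = cell_m)
}

.rowMins <- function(m) {
  # row minima without apply() overhead
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmin(out, m[, j])
  out
}
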