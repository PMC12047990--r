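#' Calinski-Harabasz clustering validity score
#'
#' Ratio of between-cluster to within-cluster dispersion, each normalized
#' by its degrees of freedom: `CH = (BCSS/(k-1)) / (WCSS/(n-k))`, where
#' BCSS is the size-weighted sum of squared distances from cluster
#' centroids to the overall centroid, and WCSS the total squared distance
#' of points to their cluster centroid. Higher is better-separated.
#'
#' @param X n x p numeric matrix.
#' @param labels cluster labels, one per row; every cluster non-empty,
#'   k >= 2 and n > k.
#' @return the CH score; `Inf` (with a warning) when WCSS is exactly 0.
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stopf("one label per row required")
  cl <- unique(labels)
  k <- length(cl); n <- nrow(X)
  if (k < 2) stopf("need at least 2 clusters")
  if (n <= k) stopf("need more points than clusters")
  overall <- colMeans(X)
  bcss <- 0; wcss <- 0
  for (c in cl) {
    idx <- labels == c
    ni <- sum(idx)
    cent <- colMeans(X[idx, , drop = FALSE])
    bcss <- bcss + ni * sum((cent - overall)^2)
    wcss <- wcss + sum(sweep(X[idx, , drop = FALSE], 2, cent)^2)
  }
  if (wcss == 0) {
    warnf("WCSS is 0 (coincident points per cluster); CH is infinite")
    return(Inf)
  }
  (bcss / (k - 1)) / (wcss / (n - k))
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation. Returns `NaN` with a warning when
#' either input has zero variance (the coefficient is undefined).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return r in \[-1, 1\], or `NaN` for degenerate input.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stopf("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("zero variance input; correlation undefined")
    return(NaN)
  }
  stats::cor(x, y, method = "pearson")
}

#' Kendall's tau-b rank correlation
#'
#' Tau-b: concordant minus discordant pairs over the geometric mean of the
#' pair counts corrected for ties in x alone and in y alone,
#' `tau = (P - Q) / sqrt((P + Q + T)(P + Q + U))`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau in \[-1, 1\], or `NaN` (with a warning) when all values of
#'   x or of y are tied.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stopf("x and y must have equal length >= 2")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warnf("all values tied; tau undefined")
    return(NaN)
  }
  stats::cor(x, y, method = "kendall")
}

#' Jensen-Shannon divergence (base-2, bounded in \[0, 1\])
#'
#' `JS(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`,
#' logarithms base 2 so the value lies in \[0, 1\] (1 exactly for disjoint
#' support). Inputs are renormalized to sum 1; `0 log 0 := 0`.
#'
#' @param P,Q nonnegative vectors of equal length with positive sums.
#' @return divergence in \[0, 1\].
#' @export
js_divergence <- function(P, Q) {
  if (length(P) != length(Q)) stopf("P and Q must have equal length")
  if (any(P < 0) || any(Q < 0)) stopf("P and Q must be nonnegative")
  if (sum(P) <= 0 || sum(Q) <= 0) stopf("P and Q must have positive sums")
  P <- P / sum(P); Q <- Q / sum(Q)
  M <- (P + Q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  d <- kl(P, M) / 2 + kl(Q, M) / 2
  min(max(d, 0), 1)
}

#' Parameters for global SSIM
#' @param L dynamic range of the maps (default: computed from the data as
#'   the larger of the two ranges).
#' @param k1,k2 stabilizer fractions; `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.
#' @return an `ssim_params` list.
#' @export
ssim_params <- function(L = NULL, k1 = 0.01, k2 = 0.03) {
  structure(list(L = L, k1 = k1, k2 = k2), class = "ssim_params")
}

#' Global structural similarity between two spatial maps
#'
#' Single whole-map SSIM (no sliding window):
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`,
#' using whole-map means, variances, and covariance. Used to compare the
#' spatial distribution of a predicted cell-type probability map against
#' the ground-truth map, both rasterized to a common grid (see
#' [rasterize_spots()]).
#'
#' @param x_map,y_map numeric arrays/vectors of identical shape.
#' @param params an [ssim_params()].
#' @return SSIM value in \[-1, 1\].
#' @export
ssim_global <- function(x_map, y_map, params = ssim_params()) {
  if (!identical(dim(x_map) %||% length(x_map),
                 dim(y_map) %||% length(y_map)))
    stopf("x_map and y_map must have identical shape")
  x <- as.numeric(x_map); y <- as.numeric(y_map)
  L <- params$L %||% max(diff(range(x)), diff(range(y)), 1e-12)
  C1 <- (params$k1 * L)^2; C2 <- (params$k2 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Rasterize spot values to a regular grid
#'
#' Nearest-spot rasterization at pitch resolution: each grid pixel takes
#' the value of the nearest spot. Gives spot-level maps a common image
#' representation for [ssim_global()].
#'
#' @param coords spot coordinates (n x 2, microns).
#' @param values numeric per-spot values.
#' @param pitch grid resolution in microns (default: spot pitch inferred
#'   from the minimum nearest-neighbor distance).
#' @return numeric matrix (rows = y, cols = x).
#' @export
rasterize_spots <- function(coords, values, pitch = NULL) {
  coords <- as.matrix(coords)
  if (is.null(pitch)) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    pitch <- max(min(d), 1e-9)
  }
  xs <- seq(min(coords[, 1]), max(coords[, 1]) + pitch / 2, by = pitch)
  ys <- seq(min(coords[, 2]), max(coords[, 2]) + pitch / 2, by = pitch)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  d2 <- outer(rowSums(grid^2), rowSums(coords^2), "+") -
    2 * grid %*% t(coords)
  nearest <- max.col(-d2, ties.method = "first")
  matrix(values[nearest], nrow = length(ys), ncol = length(xs), byrow = TRUE)
}

#' Cross-method impact scores from JS divergence and SSIM
#'
#' For each method, the per-cell-type JS divergences and SSIMs are averaged,
#' the two averages are z-scored across methods (the JS z-score inverted,
#' since lower divergence is better), and the impact score is the mean of
#' the two z-scores. By construction impact scores sum to zero across
#' methods.
#'
#' @param results named list; each element a list with numeric vectors `js`
#'   and `ssim` (one value per cell type, same types for every method).
#' @return data.frame with method, mean_js, mean_ssim, z_js (inverted),
#'   z_ssim, impact_score.
#' @export
impact_scores <- function(results) {
  if (length(results) < 2) stopf("need at least 2 methods for z-scores")
  mean_js <- vapply(results, function(r) mean(r$js), 0)
  mean_ssim <- vapply(results, function(r) mean(r$ssim), 0)
  zsafe <- function(v) {
    s <- stats::sd(v)
    if (s == 0) { warnf("zero cross-method variance; z set to 0"); v * 0 }
    else (v - mean(v)) / s
  }
  z_js <- -zsafe(mean_js)
  z_ssim <- zsafe(mean_ssim)
  data.frame(method = names(results) %||% seq_along(results),
             mean_js = mean_js, mean_ssim = mean_ssim,
             z_js = z_js, z_ssim = z_ssim,
             impact_score = (z_js + z_ssim) / 2,
             row.names = NULL)
}

#' Frequency-weighted F1 score
#'
#' Per-class `F1 = 2 TP / (2 TP + FP + FN)`, averaged with each class
#' weighted by its frequency in `y_true`; classes absent from `y_true` are
#' skipped.
#'
#' @param y_true,y_pred label vectors of equal positive length.
#' @return weighted F1 in \[0, 1\].
#' @export
weighted_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stopf("y_true and y_pred must have equal positive length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  f1 <- vapply(classes, function(c) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  wts <- vapply(classes, function(c) mean(y_true == c), 0)
  sum(f1 * wts)
}

#' Per-gene mean squared error
#' @param pred,truth aligned spots x genes matrices.
#' @return named numeric vector, one MSE per gene (mean over spots).
#' @export
mse_per_gene <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stopf("shape mismatch")
  colMeans((pred - truth)^2)
}
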