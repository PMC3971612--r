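#' Principal components of a table under Euclidean geometry
#'
#' Classical PCA of the column-centred data (equivalent to metric scaling of
#' the between-sample Euclidean distances). Deterministic up to the sign of
#' each axis.
#'
#' @param x samples x feature matrix or omics table.
#' @param n_axes number of axes to retain (default 2; truncated with a
#'   warning if it exceeds the rank).
#' @return An object of class `ordination`: list with `scores` (samples x
#'   axes), `eigenvalues` (non-increasing) and `n_axes`.
#' @export
pca_euclidean <- function(x, n_axes = 2L) {
  x <- .table_matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_axes > rank) {
    warning(sprintf("requested %d axes but rank is %d; truncating", n_axes, rank))
    n_axes <- rank
  }
  structure(list(scores = pc$x[, seq_len(n_axes), drop = FALSE],
                 eigenvalues = pc$sdev^2,
                 n_axes = as.integer(n_axes)), class = "ordination")
}

# symmetric Procrustes residual m12^2 between two centred/unit-scaled configs
.procrustes_m2 <- function(a, b) {
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  ac <- ac / sqrt(sum(ac^2))
  bc <- bc / sqrt(sum(bc^2))
  d <- svd(crossprod(ac, bc))$d
  max(1 - sum(d)^2, 0)
}

#' Symmetric Procrustes test of two ordinations
#'
#' Superimposes two sample configurations by translation, uniform scaling
#' and rigid rotation (both configurations centred and scaled to unit sum of
#' squares; the optimal rotation comes from the singular decomposition of
#' their cross-product). The statistic is the residual
#' `m12^2 = 1 - (sum of singular values)^2`; significance is assessed by
#' permuting the sample rows of the second configuration:
#' `p = (1 + #\{permutation congruence >= observed\}) / (1 + n_perm)`.
#'
#' @param a,b `ordination` objects (or score matrices) over the same samples
#'   with the same number of axes.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `concordance_result` with `statistic` (m12^2),
#'   `congruence` (`sqrt(1 - m12^2)`), `p_value`, `n_permutations`.
#' @export
procrustes_test <- function(a, b, n_perm = 999L, seed = 1L) {
  sa <- if (inherits(a, "ordination")) a$scores else as.matrix(a)
  sb <- if (inherits(b, "ordination")) b$scores else as.matrix(b)
  if (!is.null(rownames(sa)) && !is.null(rownames(sb))) {
    if (!setequal(rownames(sa), rownames(sb)))
      stop("configurations must cover the same samples")
    sb <- sb[rownames(sa), , drop = FALSE]
  }
  if (nrow(sa) != nrow(sb) || ncol(sa) != ncol(sb))
    stop("configurations must have matching dimensions")
  set.seed(seed)
  m2 <- .procrustes_m2(sa, sb)
  obs_t <- sqrt(1 - m2)
  n <- nrow(sa)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm_t <- sqrt(1 - .procrustes_m2(sa, sb[sample.int(n), , drop = FALSE]))
    if (perm_t >= obs_t) exceed <- exceed + 1L
  }
  structure(list(statistic = m2, congruence = obs_t,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = as.integer(n_perm)),
            class = "concordance_result")
}

# RV coefficient of two column-centred tables
.rv_coefficient <- function(xc, yc) {
  cxy <- crossprod(xc, yc)
  num <- sum(cxy^2)
  den <- sqrt(sum(crossprod(xc)^2) * sum(crossprod(yc)^2))
  num / den
}

#' Coinertia RV test between two omics tables
#'
#' The RV coefficient is the matrix correlation
#' `trace(X'Y Y'X) / sqrt(trace((X'X)^2) trace((Y'Y)^2))` of the
#' column-centred tables: a value in \[0, 1\] measuring global covariance
#' structure shared by the two tables over the same samples. Significance is
#' Monte Carlo, by permuting the sample rows of one table. Per-feature
#' weights are the norms of each feature's loadings on the first coinertia
#' axes (the singular directions of the cross-covariance), ranking features
#' by their contribution to the shared structure.
#'
#' @param x,y samples x feature matrices (or tables) on the same samples.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param n_axes number of coinertia axes used for the feature weights.
#' @return list of class `concordance_result` with `statistic` (RV),
#'   `p_value`, `n_permutations`, `per_feature_weights` (list `x`, `y`).
#' @export
coinertia_rv <- function(x, y, n_perm = 999L, seed = 1L, n_axes = 2L) {
  xm <- .table_matrix(x)
  ym <- .table_matrix(y)
  shared <- intersect(rownames(xm), rownames(ym))
  if (length(shared) < 3) stop("tables must share at least 3 samples")
  xc <- scale(xm[shared, , drop = FALSE], scale = FALSE)
  yc <- scale(ym[shared, , drop = FALSE], scale = FALSE)
  if (sum(xc^2) == 0 || sum(yc^2) == 0) stop("zero-variance table")
  set.seed(seed)
  rv <- .rv_coefficient(xc, yc)
  n <- nrow(xc)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (.rv_coefficient(xc[sample.int(n), , drop = FALSE], yc) >= rv)
      exceed <- exceed + 1L
  }
  sv <- svd(crossprod(xc, yc))
  ax <- seq_len(min(n_axes, length(sv$d)))
  wx <- sqrt(rowSums((sv$u[, ax, drop = FALSE] %*%
                        diag(sv$d[ax], length(ax)))^2))
  wy <- sqrt(rowSums((sv$v[, ax, drop = FALSE] %*%
                        diag(sv$d[ax], length(ax)))^2))
  names(wx) <- colnames(xc)
  names(wy) <- colnames(yc)
  structure(list(statistic = rv, p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = as.integer(n_perm),
                 per_feature_weights = list(x = wx, y = wy)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  lab <- if (!is.null(x$congruence)) "Procrustes m12^2" else "RV"
  cat(sprintf("%s = %.4f, permutation p = %.4g (%d permutations)\n",
              lab, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
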