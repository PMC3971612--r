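#' Storey q-values
#'
#' Converts a vector of p-values into q-values, the per-test FDR analogue of
#' the p-value. The proportion of true nulls `pi0` is estimated on a grid of
#' tuning values lambda = 0.05, 0.10, ..., 0.95 via
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, smoothed with a cubic
#' smoothing spline (df = 3) and extrapolated to lambda -> 1. When the
#' smoother yields an estimate outside (0, 1], `pi0` falls back to 1, in
#' which case the q-values reduce exactly to Benjamini-Hochberg adjusted
#' p-values. q-values are monotone non-decreasing in p and bounded by 1.
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @param pi0 optional fixed value for the null proportion, bypassing
#'   estimation (e.g. `pi0 = 1` for plain BH).
#' @return numeric vector of q-values in the order of `p`, with the
#'   estimated `pi0` attached as attribute `"pi0"`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (m < 100 || all(pi0_lambda == 0)) {
      1
    } else {
      fit <- try(stats::smooth.spline(lambda, pi0_lambda, df = 3), silent = TRUE)
      if (inherits(fit, "try-error")) 1 else stats::predict(fit, x = 1)$y
    }
    if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # step-up from the largest p: q(p_(i)) = min_{j >= i} pi0 m p_(j) / j
  q <- pmin(pi0 * m * p[o] / (m:1), 1)
  q <- cummin(q)[ro]
  attr(q, "pi0") <- pi0
  q
}
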