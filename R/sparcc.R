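#' SparCC compositional correlation
#'
#' Estimates basis (absolute-abundance) correlations between OTUs from
#' compositional count data. For each of `n_dirichlet` posterior draws of
#' the underlying fractions (Dirichlet with a uniform prior, which also
#' handles zero counts), the log-ratio variances
#' `T_ij = Var_samples log(f_i / f_j)` are computed; under the sparsity
#' approximation the basis variances `omega` solve the linear system
#' `sum_j T_ij = d_i omega_i + sum_j omega_j` over the included pairs, and
#' the basis correlation is
#' `rho_ij = (omega_i + omega_j - T_ij) / (2 sqrt(omega_i omega_j))`.
#' The strongest-correlated pair is then iteratively excluded from the
#' system and the solution refreshed, until no remaining pair exceeds
#' `exclusion_threshold` or the iteration cap is reached. The reported
#' matrix is the element-wise median over Dirichlet draws, clipped to
#' \[-1, 1\] with unit diagonal.
#'
#' @param counts an [otu_table()] or samples x OTU count matrix with at
#'   least 4 OTUs and 8 samples.
#' @param n_dirichlet number of Dirichlet posterior draws (default 20).
#' @param n_exclusion_iters cap on strong-pair exclusion rounds per draw
#'   (default 10).
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded from the basis-variance system (default 0.1).
#' @param seed integer seed.
#' @return list of class `sparcc_result`: `correlation` (OTU x OTU, unit
#'   diagonal), `basis_variance` (median over draws), `n_iterations`,
#'   `n_excluded_pairs` (median count over draws).
#' @export
sparcc <- function(counts, n_dirichlet = 20L, n_exclusion_iters = 10L,
                   exclusion_threshold = 0.1, seed = 1L) {
  m <- .table_matrix(counts)
  set.seed(seed)
  .sparcc_run(m, n_dirichlet, n_exclusion_iters, exclusion_threshold)
}

# core estimator; uses the current RNG stream
.sparcc_run <- function(m, n_dirichlet, n_exclusion_iters,
                        exclusion_threshold) {
  n <- nrow(m)
  d <- ncol(m)
  if (d < 4) stop("basis decomposition underdetermined: need >= 4 OTUs")
  if (n < 8) stop("need >= 8 samples")
  cors <- array(NA_real_, c(d, d, n_dirichlet))
  omegas <- matrix(NA_real_, d, n_dirichlet)
  n_excl <- integer(n_dirichlet)
  for (b in seq_len(n_dirichlet)) {
    # posterior fractions: Dirichlet(counts + 1) per sample, via gammas
    g <- matrix(stats::rgamma(n * d, shape = as.numeric(t(m)) + 1), n, d,
                byrow = TRUE)
    f <- g / rowSums(g)
    l <- log(f)
    cv <- stats::cov(l)
    v <- diag(cv)
    tt <- outer(v, v, "+") - 2 * cv  # T_ij = Var log(f_i/f_j)
    sol <- .sparcc_basis(tt, n_exclusion_iters, exclusion_threshold)
    cors[, , b] <- sol$rho
    omegas[, b] <- sol$omega
    n_excl[b] <- sol$n_excluded
  }
  rho <- apply(cors, c(1, 2), stats::median)
  rho <- pmin(pmax((rho + t(rho)) / 2, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  structure(list(correlation = rho,
                 basis_variance = stats::setNames(
                   apply(omegas, 1, stats::median), colnames(m)),
                 n_iterations = as.integer(n_exclusion_iters),
                 n_excluded_pairs = as.integer(stats::median(n_excl))),
            class = "sparcc_result")
}

# solve basis variances with iterative strong-pair exclusion
.sparcc_basis <- function(tt, n_iter, threshold) {
  d <- nrow(tt)
  included <- matrix(TRUE, d, d)
  diag(included) <- FALSE
  solve_once <- function() {
    mm <- included * 1
    diag(mm) <- rowSums(included)
    t_vec <- rowSums(tt * included)
    omega <- tryCatch(solve(mm, t_vec), error = function(e) rep(mean(t_vec) / d, d))
    omega <- pmax(omega, 1e-12)
    rho <- (outer(omega, omega, "+") - tt) / (2 * sqrt(outer(omega, omega)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    list(omega = omega, rho = rho)
  }
  sol <- solve_once()
  n_excluded <- 0L
  for (it in seq_len(n_iter)) {
    r <- abs(sol$rho)
    r[!included] <- 0
    mx <- max(r)
    if (mx <= threshold) break
    idx <- which(r == mx, arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    # keep the system identifiable: every OTU retains >= 2 partners
    if (sum(included[i, ]) <= 2 || sum(included[j, ]) <= 2) break
    included[i, j] <- included[j, i] <- FALSE
    n_excluded <- n_excluded + 1L
    sol <- solve_once()
  }
  c(sol, list(n_excluded = n_excluded))
}

#' @export
print.sparcc_result <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  cat(sprintf("sparcc_result: %d OTUs, mean |rho| %.3f, %d pair(s) excluded\n",
              nrow(x$correlation), mean(abs(off)), x$n_excluded_pairs))
  invisible(x)
}
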