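test_that("soft-threshold selection admits high powers and matches the fit oracle", {
  b <- block_metabolites(n = 30, sizes = c(10, 10), rho = 0.85, n_noise = 10)
  res <- pick_soft_threshold(b$x)
  expect_true(all(c(22, 32) %in% res$fit_table$power))
  expect_true(res$power %in% res$fit_table$power)
  # brute-force regression oracle for the scale-free index at one beta
  beta <- 4
  a <- abs(cor(b$x))^beta
  diag(a) <- 0
  k <- rowSums(a)
  breaks <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, breaks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & km > 0
  fit <- lm(log10(pk[ok]) ~ log10(km[ok]))
  oracle_r2 <- summary(fit)$r.squared * (coef(fit)[2] < 0)
  expect_equal(res$fit_table$r_squared[res$fit_table$power == beta],
               unname(oracle_r2), tolerance = 1e-10)
})

test_that("beta = 1 adjacency is |Pearson| and constant columns are dropped", {
  b <- block_metabolites(n = 25, sizes = c(6, 6), rho = 0.8)
  x <- cbind(b$x, const = rep(2, 25))
  expect_warning(res <- pick_soft_threshold(x, candidate_powers = 1:3),
                 "constant")
  a1 <- abs(cor(b$x))
  diag(a1) <- 0
  expect_equal(res$fit_table$mean_k[1], mean(rowSums(a1)), tolerance = 1e-12)
})

test_that("TOM dissimilarity matches the direct formula on edge and random cases", {
  # empty graph: dissimilarity 1 off-diagonal
  z <- matrix(0, 4, 4)
  dz <- tom_dissimilarity(z)
  expect_equal(dz[upper.tri(dz)], rep(1, 6))
  expect_equal(diag(dz), rep(0, 4))
  # perfect clique: dissimilarity 0
  cl <- matrix(1, 3, 3); diag(cl) <- 0
  expect_equal(max(abs(tom_dissimilarity(cl))), 0)
  # random 5-node adjacency vs the naive double-loop oracle
  for (s in 1:5) {
    a <- random_adjacency(5, seed = s)
    expect_equal(tom_dissimilarity(a), naive_tom_dissimilarity(a),
                 tolerance = 1e-10)
  }
  expect_error(tom_dissimilarity(matrix(runif(9), 3)), "symmetric")
})

test_that("planted blocks are recovered as exactly two modules", {
  b <- block_metabolites(n = 40, sizes = c(12, 13), rho = 0.9)
  a <- abs(cor(b$x))^6
  diag(a) <- 0
  d <- tom_dissimilarity(a)
  dimnames(d) <- list(colnames(b$x), colnames(b$x))
  ms <- detect_modules(d, min_size = 10, x = b$x)
  mods <- setdiff(unique(ms$assignment), "unclustered")
  expect_length(mods, 2)
  expect_equal(mclust::adjustedRandIndex(ms$assignment, b$truth), 1)
  # permutation invariance: same partition after column shuffling
  set.seed(5)
  perm <- sample(ncol(d))
  ms2 <- detect_modules(d[perm, perm], min_size = 10)
  expect_equal(mclust::adjustedRandIndex(ms2$assignment[names(ms$assignment)],
                                         ms$assignment), 1)
})

test_that("fewer metabolites than the minimum module size stay unclustered", {
  b <- block_metabolites(n = 30, sizes = c(4, 5), rho = 0.9)
  ms <- metabolite_modules(b$x, power = 6, min_size = 10)
  expect_true(all(ms$assignment == "unclustered"))
  expect_equal(formals(detect_modules)$min_size, 10L)
})

test_that("eigenmetabolites agree with the SVD oracle and orientation rule", {
  # identical members: profile is the shared standardised profile, ve = 1
  set.seed(8)
  v <- rnorm(10)
  x <- cbind(a = v, b = v, c = v)
  rownames(x) <- paste0("S", 1:10)
  e <- eigenmetabolite(x)
  zs <- as.numeric(scale(v))
  expect_equal(abs(cor(e$profile, zs)), 1, tolerance = 1e-12)
  expect_equal(e$variance_explained, 1, tolerance = 1e-12)
  expect_gt(mean(cor(e$profile, scale(x))), 0)
  # flipping all members flips the oriented profile with it (orientation
  # keeps the mean member correlation positive)
  ef <- eigenmetabolite(-x)
  expect_equal(ef$profile, -e$profile, tolerance = 1e-12)
  expect_gt(mean(cor(ef$profile, scale(-x))), 0)
  # small instance vs direct SVD
  set.seed(9)
  y <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("S", 1:4), NULL))
  ey <- eigenmetabolite(y)
  sv <- svd(scale(y))
  u1 <- sv$u[, 1]
  if (mean(cor(u1, scale(y))) < 0) u1 <- -u1
  expect_equal(unname(ey$profile), u1, tolerance = 1e-10)
  expect_equal(ey$variance_explained, sv$d[1]^2 / sum(sv$d^2),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(ey$profile^2)), 1, tolerance = 1e-12)
  expect_error(eigenmetabolite(matrix(1, 5, 3)), "constant")
})

test_that("module validation reports clean separation for planted blocks", {
  b <- block_metabolites(n = 50, sizes = c(12, 14), rho = 0.9, seed = 3)
  ms <- metabolite_modules(b$x, power = 6)
  v <- validate_modules(ms, b$x)
  expect_gt(v$mean_silhouette, 0)
  expect_equal(v$kmeans_agreement, 1)
  expect_equal(v$plain_hclust_agreement, 1)
  expect_gt(v$cophenetic_corr, 0.5)
})

test_that("combining modules with unclustered metabolites counts columns", {
  b <- block_metabolites(n = 40, sizes = c(12, 13), rho = 0.9, n_noise = 7)
  ms <- metabolite_modules(b$x, power = 6)
  n_mod <- length(setdiff(unique(ms$assignment), "unclustered"))
  n_uncl <- sum(ms$assignment == "unclustered")
  combined <- combine_with_unclustered(ms, b$x)
  expect_equal(ncol(combined), n_mod + n_uncl)
  expect_equal(nrow(combined), nrow(b$x))
  # no modules: output is the input matrix
  noise <- block_metabolites(n = 20, sizes = integer(0), rho = 0.5,
                             n_noise = 12, seed = 4)
  ms0 <- metabolite_modules(noise$x, power = 6)
  expect_equal(combine_with_unclustered(ms0, noise$x), noise$x)
})

test_that("variance explained stays in (0, 1] across random modules", {
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("S", 1:10), NULL))
    e <- eigenmetabolite(x)
    expect_gt(e$variance_explained, 0)
    expect_lte(e$variance_explained, 1)
  }
})
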