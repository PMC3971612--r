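profile_fixture <- function(n_per = 8, k = 3, p = 6, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p, sd = sep), k)
  x <- do.call(rbind, lapply(seq_len(k), function(g) {
    sweep(matrix(rnorm(n_per * p), n_per), 2, centers[g, ], "+")
  }))
  rownames(x) <- sprintf("OTU%02d", seq_len(nrow(x)))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

test_that("profile matrix keeps analytes with >= 2 significant OTU edges", {
  rho <- matrix(runif(12, -1, 1), 4, 3,
                dimnames = list(paste0("OTU", 1:4), paste0("m", 1:3)))
  net <- data.frame(
    otu_id = rep(rownames(rho), 3), analyte_id = rep(colnames(rho), each = 4),
    rho = as.numeric(rho), p = 0.01,
    q = c(0.1, 0.1, 0.5, 0.5,   # m1: two significant edges -> included
          0.1, 0.5, 0.5, 0.5,   # m2: one -> excluded
          0.5, 0.5, 0.5, 0.5))  # m3: none -> excluded
  class(net) <- c("interomic_network", "data.frame")
  attr(net, "rho_matrix") <- rho
  prof <- correlation_profile_matrix(net)
  expect_equal(colnames(prof), "m1")
  expect_equal(prof[, "m1"], rho[, "m1"])  # raw rho, not thresholded
  # NA cells are imputed as zero and counted
  rho2 <- rho; rho2["OTU4", "m1"] <- NA
  attr(net, "rho_matrix") <- rho2
  prof2 <- correlation_profile_matrix(net)
  expect_equal(prof2["OTU4", "m1"], 0)
  expect_equal(attr(prof2, "n_imputed"), 1L)
  net$q <- 0.5
  expect_error(correlation_profile_matrix(net), "significant")
})

test_that("complete-linkage clustering recovers planted profile groups", {
  f <- profile_fixture()
  ca <- cluster_otus(f$x, 3)
  expect_equal(mclust::adjustedRandIndex(ca$cluster, f$truth), 1)
  expect_equal(sort(unique(ca$cluster)), 1:3)
  expect_false(is.na(ca$cut_height))
  # k = 1 puts everything together
  ca1 <- cluster_otus(f$x, 1)
  expect_equal(unname(unique(ca1$cluster)), 1L)
  expect_error(cluster_otus(f$x, 99), "exceeds")
  # invariant to OTU input order (same partition after relabelling)
  set.seed(2)
  perm <- sample(nrow(f$x))
  ca_p <- cluster_otus(f$x[perm, ], 3)
  expect_equal(mclust::adjustedRandIndex(ca_p$cluster[names(ca$cluster)],
                                         ca$cluster), 1)
})

test_that("tied merge heights trigger the split-refinement path", {
  # 4 equidistant points (regular tetrahedron) cannot be cut into 3 groups
  # at any single height
  x <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3,
              byrow = TRUE, dimnames = list(paste0("OTU", 1:4), NULL))
  d <- dist(x)
  expect_true(max(abs(as.numeric(d) - sqrt(8))) < 1e-12)
  expect_message(ca <- cluster_otus(x, 3), "no cut height")
  expect_equal(length(unique(ca$cluster)), 3L)
  expect_true(is.na(ca$cut_height))
})

test_that("prediction strength selects the planted cluster number", {
  f <- profile_fixture(n_per = 12, k = 3, sep = 8, seed = 7)
  ps <- prediction_strength(f$x, k_range = 2:5, n_splits = 20, seed = 3)
  expect_equal(ps$k_star, 3L)
  expect_true(all(ps$ps_curve$ps >= 0 & ps$ps_curve$ps <= 1))
  expect_equal(ps$ps_curve$ps[ps$ps_curve$k == 1], 1)
})

test_that("cluster compositions are per-phylum fractions summing to one", {
  tax <- c(
    OTU1 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__A;s__",
    OTU2 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__B;s__",
    OTU3 = "k__Bacteria;p__Bacteroidetes;c__;o__;f__;g__C;s__",
    OTU4 = "k__Bacteria;p__Proteobacteria;c__;o__;f__;g__D;s__")
  ca <- structure(list(cluster = c(OTU1 = 1L, OTU2 = 1L, OTU3 = 1L, OTU4 = 2L),
                       k = 2L), class = "cluster_assignment")
  comp <- cluster_composition(ca, tax)
  expect_equal(sum(comp$cluster_1), 1)
  expect_equal(unname(comp$cluster_1["Firmicutes"]), 2 / 3)
  expect_equal(unname(comp$cluster_2["Proteobacteria"]), 1)
})

test_that("cross-region overlap uses one-sided Fisher with Bonferroni flags", {
  # toy 2x2 (a=5, b=1, c=1, d=13): p equals the explicit tail sum
  p_oracle <- hyper_tail_oracle(5, 1, 1, 13)
  c1 <- c(rep(1L, 6), rep(2L, 14))
  c2 <- c(rep(1L, 5), 2L, 1L, rep(2L, 13))
  names(c1) <- names(c2) <- sprintf("OTU%02d", 1:20)
  ca1 <- structure(list(cluster = c1, k = 2L), class = "cluster_assignment")
  ca2 <- structure(list(cluster = c2, k = 2L), class = "cluster_assignment")
  ov <- cross_region_overlap(ca1, ca2)
  row <- ov[ov$cluster1 == 1 & ov$cluster2 == 1, ]
  expect_equal(row$overlap, 5L)
  expect_equal(row$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(row$p_bonferroni, min(1, p_oracle * 4), tolerance = 1e-12)
  expect_equal(row$significant, row$p_bonferroni < 0.05)
  expect_equal(unname(fisher.test(matrix(c(5, 1, 1, 13), 2),
                                  alternative = "greater")$p.value),
               row$p_value, tolerance = 1e-10)
  # empty overlap cell: P(X >= 0) = 1
  c3 <- stats::setNames(rep(c(2L, 1L), c(6, 14)), names(c1))
  ca3 <- structure(list(cluster = c3, k = 2L), class = "cluster_assignment")
  ov2 <- cross_region_overlap(ca1, ca3)
  expect_equal(ov2$p_value[ov2$cluster1 == 1 & ov2$cluster2 == 1], 1)
})
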