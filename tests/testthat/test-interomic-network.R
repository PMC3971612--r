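net_fixture <- function(seed = 1, n = 20, p_otu = 6, p_met = 5) {
  set.seed(seed)
  x <- matrix(rexp(n * p_otu), n, dimnames = list(paste0("S", 1:n),
                                                  paste0("OTU", 1:p_otu)))
  y <- matrix(rexp(n * p_met), n, dimnames = list(paste0("S", 1:n),
                                                  paste0("m", 1:p_met)))
  list(x = x, y = y)
}

test_that("Spearman edges are rank correlations with midrank ties", {
  f <- net_fixture()
  y <- f$y
  y[, 1] <- f$x[, 1]          # identical vector: rho = 1
  y[, 2] <- exp(3 * f$x[, 2]) # strictly increasing transform: rho = 1
  net <- spearman_all_pairs(f$x, y)
  e <- function(o, a) net[net$otu_id == o & net$analyte_id == a, ]
  expect_equal(e("OTU1", "m1")$rho, 1)
  expect_equal(e("OTU2", "m2")$rho, 1)
  # rank invariance: a strictly increasing transform of an analyte leaves
  # every edge rho (and p) unchanged
  y2 <- f$y
  y2[, 3] <- exp(2 * f$y[, 3]) - 1
  raw <- spearman_all_pairs(f$x, f$y)
  trans <- spearman_all_pairs(f$x, y2)
  expect_equal(trans$rho[trans$analyte_id == "m3"],
               raw$rho[raw$analyte_id == "m3"], tolerance = 1e-12)
  expect_equal(trans$p[trans$analyte_id == "m3"],
               raw$p[raw$analyte_id == "m3"], tolerance = 1e-12)
})

test_that("a 6-sample tie case matches the midrank Pearson-on-ranks oracle", {
  x <- matrix(c(1, 2, 2, 3, 4, 5), 6, 1,
              dimnames = list(paste0("S", 1:6), "OTU1"))
  y <- matrix(c(2, 1, 4, 3, 6, 5), 6, 1,
              dimnames = list(paste0("S", 1:6), "m1"))
  net <- spearman_all_pairs(x, y)
  oracle <- cor(rank(x[, 1]), rank(y[, 1]))  # Pearson on midranks
  expect_equal(net$rho, oracle, tolerance = 1e-12)
})

test_that("zero-variance pairs are excluded with a logged count", {
  f <- net_fixture()
  f$x[, 3] <- 7
  expect_message(net <- spearman_all_pairs(f$x, f$y), "zero-variance")
  expect_false("OTU3" %in% net$otu_id)
  expect_equal(attr(net, "n_excluded_pairs"), ncol(f$y))
  expect_true(all(is.na(attr(net, "rho_matrix")["OTU3", ])))
})

test_that("merging requires at least 4 shared samples", {
  f <- net_fixture(n = 6)
  y <- f$y
  rownames(y) <- paste0("T", 1:6)
  rownames(y)[1:3] <- rownames(f$x)[1:3]
  expect_error(spearman_all_pairs(f$x, y), "fewer than 4")
})

test_that("q-values reduce to Benjamini-Hochberg with pi0 fixed at 1", {
  p <- c(0.62, 0.001, 0.04, 0.9, 0.013, 0.2, 0.35, 0.008, 1, 0.07)
  q <- qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(as.numeric(qvalues(rep(1, 5))), rep(1, 5))
  expect_error(qvalues(c(0.5, 0)), "0, 1")
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("q-values are order-preserving and permutation invariant", {
  set.seed(42)
  p <- runif(200)^1.5
  q <- as.numeric(qvalues(p))
  expect_true(all(diff(q[order(p)]) >= -1e-14))
  perm <- sample(200)
  expect_equal(as.numeric(qvalues(p[perm])), q[perm], tolerance = 1e-12)
  expect_true(all(q <= 1))
})

test_that("significance thresholding is strict at q < 0.2", {
  f <- net_fixture()
  net <- spearman_all_pairs(f$x, f$y)
  net$q <- seq(0.01, 0.3, length.out = nrow(net))
  net$q[1] <- 0.19
  net$q[2] <- 0.20
  sig <- significant_edges(net, 0.2)
  expect_true(paste(net$otu_id[1], net$analyte_id[1]) %in%
                paste(sig$otu_id, sig$analyte_id))
  expect_false(paste(net$otu_id[2], net$analyte_id[2]) %in%
                 paste(sig$otu_id, sig$analyte_id))
  empty <- net[0, ]
  class(empty) <- c("interomic_network", "data.frame")
  expect_equal(nrow(significant_edges(empty)), 0L)
})

test_that("genus binning collapses duplicate metabolite correlations", {
  tax <- c(
    OTU1 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__Blautia;s__",
    OTU2 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__Blautia;s__",
    OTU3 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__Blautia;s__",
    OTU4 = "k__Bacteria;p__Bacteroidetes;c__;o__;f__;g__Bacteroides;s__",
    OTU5 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__;s__")
  net <- data.frame(
    otu_id = c("OTU1", "OTU2", "OTU3", "OTU4", "OTU4", "OTU4", "OTU5"),
    analyte_id = c("m1", "m1", "m1", "m1", "m2", "m3", "m9"),
    rho = 0.5, p = 0.01, q = 0.1)
  class(net) <- c("interomic_network", "data.frame")
  out <- bin_by_genus(net, tax)
  # three Blautia OTUs hitting one metabolite count once
  expect_equal(out$n_unique_metabolites[out$genus == "Blautia"], 1L)
  expect_equal(out$n_unique_metabolites[out$genus == "Bacteroides"], 3L)
  # OTU5 lacks genus resolution and is excluded entirely
  expect_false(any(grepl("m9", out$genus)))
  expect_equal(nrow(out), 2L)
  # brute-force set-union oracle
  expect_equal(out$n_unique_metabolites[out$genus == "Bacteroides"],
               length(unique(net$analyte_id[net$otu_id == "OTU4"])))
})

test_that("network summaries count nodes, edges and per-phylum ratios", {
  # 10 Firmicutes detected, 3 with edges -> ratio 0.30
  tax <- setNames(rep("k__Bacteria;p__Firmicutes;c__;o__;f__;g__X;s__", 10),
                  paste0("OTU", 1:10))
  counts <- matrix(1, 4, 10, dimnames = list(paste0("S", 1:4), names(tax)))
  otus <- otu_table(counts, tax)
  net <- data.frame(otu_id = c("OTU1", "OTU2", "OTU3", "OTU1"),
                    analyte_id = c("m1", "m1", "m2", "m2"),
                    rho = 0.4, p = 0.01, q = 0.1)
  class(net) <- c("interomic_network", "data.frame")
  s <- summarize_network(net, otus)
  expect_equal(s$total_edges, 4L)
  expect_equal(s$unique_otu_nodes, 3L)
  expect_equal(s$unique_analyte_nodes, 2L)
  expect_equal(unname(s$per_phylum_ratio["Firmicutes"]), 0.30)
  expect_equal(s$mean_edges_per_analyte, s$total_edges / s$unique_analyte_nodes)
  empty <- net[0, ]
  class(empty) <- c("interomic_network", "data.frame")
  s0 <- summarize_network(empty, otus)
  expect_equal(s0$total_edges, 0L)
  expect_equal(unname(s0$per_phylum_ratio["Firmicutes"]), 0)
})

test_that("recovered planted edges carry the planted signs", {
  cfg <- synth_config(seed = 21, n_subjects = 30, n_otus = 80,
                      n_metabolites = 60, n_modules = 0,
                      module_size_range = c(0, 0), n_planted_links = 12,
                      link_effect = 0.7, frac_negative_links = 0.5,
                      n_guilds = 0, guild_size = 0, read_depth_mean = 4000,
                      n_pathways = 5)
  ds <- generate_paired_dataset(cfg)
  relab <- sweep(ds$region1$otu$counts, 1, rowSums(ds$region1$otu$counts), "/")
  net <- spearman_all_pairs(relab, log(ds$region1$metabolites$intensities))
  sig <- significant_edges(net)
  tl <- ds$truth$link_list
  tl$analyte_id <- paste0("R1_", tl$metabolite_id)
  hit <- merge(as.data.frame(sig), tl, by = c("otu_id", "analyte_id"))
  expect_gt(nrow(hit), 0)
  expect_true(all(sign(hit$rho) == hit$sign))
})
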