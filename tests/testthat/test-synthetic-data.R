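small_cfg <- function(...) {
  defaults <- list(seed = 3, n_subjects = 24, n_otus = 60, n_metabolites = 50,
                   n_modules = 2, module_size_range = c(10, 12),
                   n_planted_links = 8, read_depth_mean = 2000,
                   n_pathways = 10)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is a deterministic function of the config", {
  a <- generate_paired_dataset(small_cfg())
  b <- generate_paired_dataset(small_cfg())
  expect_identical(a, b)
  d <- generate_paired_dataset(small_cfg(seed = 4))
  expect_false(identical(a$region1$otu$counts, d$region1$otu$counts))
})

test_that("invalid configurations name the violated invariant", {
  expect_error(synth_config(read_depth_mean = 0), "read_depth_mean")
  expect_error(synth_config(n_modules = 30, module_size_range = c(10, 12),
                            n_metabolites = 50), "module size")
  expect_error(synth_config(link_effect = 1.5), "link_effect")
  expect_error(synth_config(guild_corr = 1), "guild_corr")
})

test_that("counts respect multinomial conservation and planted structure exists", {
  ds <- generate_paired_dataset(small_cfg())
  counts <- ds$region1$otu$counts
  expect_true(all(counts == round(counts)))
  expect_true(all(counts >= 0))
  # depths vary around the configured mean (Poisson draw per sample)
  expect_gt(length(unique(rowSums(counts))), 1)
  expect_lt(abs(mean(rowSums(counts)) - 2000), 3 * sqrt(2000 / 24) * 2)
  truth <- ds$truth
  expect_true(all(truth$link_list$otu_id %in% colnames(counts)))
  expect_true(all(paste0("R1_", truth$link_list$metabolite_id) %in%
                    colnames(ds$region1$metabolites$intensities)))
  expect_true(all(truth$pathway_link$pathway_id %in%
                    colnames(ds$region1$pathways$abundance)))
  # basis correlation is a valid correlation matrix
  expect_true(isSymmetric(truth$basis_correlation))
  expect_equal(unname(diag(truth$basis_correlation)),
               rep(1, ncol(counts)))
})

test_that("null configuration has exactly zero planted basis correlation", {
  cfg <- small_cfg(n_planted_links = 0, n_guilds = 0, guild_size = 0,
                   guild_corr = 0)
  ds <- generate_paired_dataset(cfg)
  s <- ds$truth$basis_correlation
  expect_identical(mean(abs(s[upper.tri(s)])), 0)
  expect_identical(nrow(ds$truth$link_list), 0L)
})

test_that("taxonomy spans at least five phyla, dominated by the two major ones", {
  cfg <- synth_config(seed = 9, n_subjects = 12, n_otus = 400,
                      n_metabolites = 30, n_modules = 0,
                      module_size_range = c(0, 0), n_planted_links = 0,
                      n_guilds = 0, guild_size = 0, read_depth_mean = 500,
                      n_pathways = 5)
  ds <- generate_paired_dataset(cfg)
  ph <- table(syntropy:::.tax_rank(ds$region1$otu$taxonomy, "phylum"))
  expect_gte(length(ph), 5)
  top2 <- sort(ph, decreasing = TRUE)[1:2]
  expect_setequal(names(top2), c("Bacteroidetes", "Firmicutes"))
  expect_gt(sum(top2) / sum(ph), 0.6)
})

test_that("planted link Spearman at n=200 falls in the oracle resimulation interval", {
  # central 95% interval of the sample Spearman over 1,000 independent
  # redraws of the same generative model (scripts/oracles.R, oracle 3)
  oracle_interval <- c(0.622, 0.759)
  cfg <- synth_config(seed = 77, n_subjects = 200, n_otus = 50,
                      n_metabolites = 20, n_modules = 0,
                      module_size_range = c(0, 0), n_planted_links = 1,
                      link_effect = 0.7, frac_negative_links = 0,
                      n_guilds = 0, guild_size = 0, read_depth_mean = 10000,
                      n_pathways = 5)
  ds <- generate_paired_dataset(cfg)
  l <- ds$truth$link_list
  relab <- sweep(ds$region1$otu$counts, 1, rowSums(ds$region1$otu$counts), "/")
  r <- cor(relab[, l$otu_id],
           ds$region1$metabolites$intensities[, paste0("R1_", l$metabolite_id)],
           method = "spearman")
  expect_gte(r, oracle_interval[1])
  expect_lte(r, oracle_interval[2])
})

test_that("shared metabolites satisfy the cross-region match tolerances", {
  cfg <- small_cfg(mass_jitter_sd = 0.001, rt_jitter_sd = 0.01,
                   shared_metabolite_fraction = 0.6)
  ds <- generate_paired_dataset(cfg)
  pairs <- ds$truth$shared_metabolite_pairs
  m1 <- ds$region1$metabolites$feature_meta
  m2 <- ds$region2$metabolites$feature_meta
  dmz <- abs(m1$mz[match(pairs$feature_region1, m1$feature_id)] -
               m2$mz[match(pairs$feature_region2, m2$feature_id)])
  drt <- abs(m1$rt[match(pairs$feature_region1, m1$feature_id)] -
               m2$rt[match(pairs$feature_region2, m2$feature_id)])
  # jitter is the difference of one N(0, sd) draw; essentially all pairs
  # sit far inside the 0.005 / 0.04 tolerances at these jitter levels
  expect_true(all(dmz <= 0.005))
  expect_true(all(drt <= 0.04))
  # region-unique features are separated from all shared masses by > 0.01
  uniq2 <- setdiff(m2$feature_id, pairs$feature_region2)
  gap <- outer(m2$mz[match(uniq2, m2$feature_id)],
               m1$mz[match(pairs$feature_region1, m1$feature_id)],
               function(a, b) abs(a - b))
  expect_true(all(gap > 0.01))
})

test_that("bundle writer round-trips through the readers", {
  ds <- generate_paired_dataset(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_dataset_bundle(ds$region1, dir, truth = ds$truth)
  otu <- read_otu_table(paths["otu"])
  expect_equal(otu$counts, ds$region1$otu$counts)
  expect_equal(otu$taxonomy, ds$region1$otu$taxonomy)
  mets <- read_metabolite_table(paths["metabolites"])
  expect_equal(mets$intensities, ds$region1$metabolites$intensities,
               tolerance = 1e-12)
  pw <- read_pathway_profile(paths["pathways"])
  expect_equal(pw$abundance, ds$region1$pathways$abundance, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "truth_links.tsv")))
})
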