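#!/usr/bin/env Rscript
# Monte-Carlo oracle simulations whose central intervals are frozen into the
# test suite. Re-run from the repository root after installing the package:
#   Rscript scripts/oracles.R
# Each oracle re-simulates the generative model many times and prints the
# central 95% interval of the statistic that the corresponding test checks
# once at a fixed seed.

suppressMessages(library(syntropy))

# ---- oracle 1: planted-link sensitivity under the study conditions --------
# 46 samples, 300 OTUs, 200 metabolites, 30 planted links at |Spearman| 0.6.
# Distribution of the per-replicate fraction of planted links recovered at
# q < 0.2 by the package's own network stage.
sens_one <- function(seed) {
  cfg <- synth_config(seed = seed, n_guilds = 0, guild_size = 0)
  ds <- generate_paired_dataset(cfg)
  relab <- sweep(ds$region1$otu$counts, 1, rowSums(ds$region1$otu$counts), "/")
  net <- spearman_all_pairs(relab, log(ds$region1$metabolites$intensities), seed = seed)
  sig <- significant_edges(net, 0.2)
  planted <- paste(ds$truth$link_list$otu_id,
                   paste0("R1_", ds$truth$link_list$metabolite_id))
  mean(planted %in% paste(sig$otu_id, sig$analyte_id))
}
n_rep <- 500
sens <- vapply(seq_len(n_rep) + 10000, sens_one, numeric(1))
cat(sprintf("planted-link sensitivity: mean %.3f, central 95%% interval [%.3f, %.3f]\n",
            mean(sens), quantile(sens, 0.025), quantile(sens, 0.975)))

# ---- oracle 2: SparCC planted-pair estimate -------------------------------
# 50 OTUs, 100 samples, one planted basis correlation 0.8 (a 2-OTU guild).
sparcc_one <- function(seed) {
  cfg <- synth_config(seed = seed, n_subjects = 100, n_otus = 50,
                      n_metabolites = 20, n_modules = 0,
                      module_size_range = c(0, 0), n_planted_links = 0,
                      n_guilds = 1, guild_size = 2, guild_corr = 0.8,
                      read_depth_mean = 20000, n_pathways = 5)
  ds <- generate_paired_dataset(cfg)
  pair <- names(which(!is.na(ds$truth$guild_assignment)))
  fit <- sparcc(ds$region1$otu, seed = seed + 1)
  fit$correlation[pair[1], pair[2]]
}
est <- vapply(seq_len(300) + 20000, sparcc_one, numeric(1))
cat(sprintf("sparcc planted 0.8 estimate: mean %.3f, central 95%% interval [%.3f, %.3f]\n",
            mean(est), quantile(est, 0.025), quantile(est, 0.975)))

# ---- oracle 3: single planted link at n = 200, effect 0.7 -----------------
# Distribution of the sample Spearman between the linked OTU's relative
# abundance and the linked metabolite.
link_one <- function(seed) {
  cfg <- synth_config(seed = seed, n_subjects = 200, n_otus = 50,
                      n_metabolites = 20, n_modules = 0,
                      module_size_range = c(0, 0), n_planted_links = 1,
                      link_effect = 0.7, frac_negative_links = 0,
                      n_guilds = 0, guild_size = 0,
                      read_depth_mean = 10000, n_pathways = 5)
  ds <- generate_paired_dataset(cfg)
  l <- ds$truth$link_list
  relab <- sweep(ds$region1$otu$counts, 1, rowSums(ds$region1$otu$counts), "/")
  cor(relab[, l$otu_id], ds$region1$metabolites$intensities[, paste0("R1_", l$metabolite_id)],
      method = "spearman")
}
rs <- vapply(seq_len(1000) + 30000, link_one, numeric(1))
cat(sprintf("planted 0.7 link sample Spearman: mean %.3f, central 95%% interval [%.3f, %.3f]\n",
            mean(rs), quantile(rs, 0.025), quantile(rs, 0.975)))
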