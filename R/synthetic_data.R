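#' Configuration for the paired-region synthetic data generator
#'
#' Defines the generative model for paired "cecum"/"sigmoid"-style datasets
#' with known planted structure: guild-structured compositional counts,
#' metabolite modules driven by shared latent factors, signed OTU-metabolite
#' links, pathway profiles concordant with the links, and metabolites shared
#' across regions within stated mass/RT jitter.
#'
#' Defaults correspond to the study design the generator emulates: 46
#' subjects per region, sequencing depth around 30,000 reads per sample,
#' 300 OTUs, 200 metabolite features, 3 modules of 15-25 metabolites with
#' within-module correlation 0.8, 30 planted links at target |Spearman| 0.6,
#' and 3 planted guilds of 10 OTUs at basis correlation 0.7.
#'
#' @param seed integer seed; the whole generated pair is a deterministic
#'   function of the configuration including this seed.
#' @param n_subjects samples per region.
#' @param n_otus,n_metabolites,n_pathways table dimensions.
#' @param n_modules number of planted metabolite modules.
#' @param module_size_range integer pair, smallest and largest module size.
#' @param module_corr within-module pairwise correlation of members (via a
#'   shared latent factor).
#' @param n_planted_links number of planted OTU-metabolite links.
#' @param link_effect target |Spearman| of a planted link, in (0, 1].
#' @param frac_negative_links fraction of planted links with negative sign.
#' @param n_guilds,guild_size,guild_corr planted co-occurring OTU guilds:
#'   blocks of `guild_size` OTUs whose basis log-abundances correlate at
#'   `guild_corr`.
#' @param read_depth_mean mean sequencing depth; per-sample depths are
#'   Poisson around this so rarefaction is exercised nontrivially.
#' @param shared_metabolite_fraction fraction of metabolites present in both
#'   regions.
#' @param mass_jitter_sd,rt_jitter_sd measurement jitter (m/z and minutes)
#'   applied to the second region's copies of shared metabolites.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_subjects = 46L,
                         n_otus = 300L,
                         n_metabolites = 200L,
                         n_modules = 3L,
                         module_size_range = c(15L, 25L),
                         module_corr = 0.8,
                         n_planted_links = 30L,
                         link_effect = 0.6,
                         frac_negative_links = 0.3,
                         n_guilds = 3L,
                         guild_size = 10L,
                         guild_corr = 0.7,
                         read_depth_mean = 30000L,
                         n_pathways = 40L,
                         shared_metabolite_fraction = 0.55,
                         mass_jitter_sd = 0.001,
                         rt_jitter_sd = 0.01) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              n_otus = as.integer(n_otus),
              n_metabolites = as.integer(n_metabolites),
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              module_corr = module_corr,
              n_planted_links = as.integer(n_planted_links),
              link_effect = link_effect,
              frac_negative_links = frac_negative_links,
              n_guilds = as.integer(n_guilds),
              guild_size = as.integer(guild_size),
              guild_corr = guild_corr,
              read_depth_mean = as.integer(read_depth_mean),
              n_pathways = as.integer(n_pathways),
              shared_metabolite_fraction = shared_metabolite_fraction,
              mass_jitter_sd = mass_jitter_sd, rt_jitter_sd = rt_jitter_sd)
  .validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

.validate_synth_config <- function(cfg) {
  err <- function(inv) stop("invalid synth_config: ", inv, call. = FALSE)
  if (cfg$read_depth_mean <= 0) err("read_depth_mean > 0")
  if (cfg$n_modules * max(cfg$module_size_range) > cfg$n_metabolites)
    err("n_modules x max module size <= n_metabolites")
  if (cfg$n_planted_links > cfg$n_otus * cfg$n_metabolites)
    err("n_planted_links <= n_otus x n_metabolites")
  if (cfg$link_effect <= 0 || cfg$link_effect > 1)
    err("link_effect in (0, 1]")
  if (cfg$frac_negative_links < 0 || cfg$frac_negative_links > 1)
    err("frac_negative_links in [0, 1]")
  if (abs(cfg$guild_corr) >= 1) err("guild_corr in (-1, 1)")
  if (cfg$module_corr <= 0 || cfg$module_corr >= 1)
    err("module_corr in (0, 1)")
  if (cfg$n_guilds * cfg$guild_size > cfg$n_otus)
    err("n_guilds x guild_size <= n_otus")
  if (cfg$shared_metabolite_fraction < 0 || cfg$shared_metabolite_fraction > 1)
    err("shared_metabolite_fraction in [0, 1]")
  invisible(cfg)
}

# Gaussian-copula coefficient giving population Spearman rho_s
.spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# normal scores of a vector (midranks for ties)
.normal_scores <- function(x) {
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

#' Generate a paired-region synthetic dataset with known ground truth
#'
#' Draws two region datasets ("region1"/"region2") from one generative model:
#' OTU counts are multinomial at Poisson-varying depth over softmax-normalised
#' log-normal basis abundances with guild block correlation; metabolite
#' log-intensities are latent-factor module members, independent noise, or
#' (for planted links) a rank-preserving function of the linked OTU's relative
#' abundance with the planted sign; per-OTU pathway profiles carry, for each
#' linked pathway, a monotone function of each OTU's expected correlation with
#' the linked metabolite; a pure-birth phylogeny covers the OTUs; taxonomy
#' strings span at least five phyla with Bacteroidetes/Firmicutes dominant.
#'
#' A `shared_metabolite_fraction` of metabolite identities (always including
#' all module members and planted-link metabolites) occurs in both regions,
#' with small normal m/z and RT jitter in the second region; region-unique
#' identities have masses separated by more than 0.01 m/z from all shared
#' masses.
#'
#' @param cfg a [synth_config()].
#' @return A list with elements `region1`, `region2` (each a `dataset_bundle`:
#'   `otu`, `metabolites`, `pathways`, `tree`, `region`) and `truth` (a
#'   `ground_truth`: `link_list`, `module_assignment`, `module_factors` per
#'   region, `guild_assignment`, `basis_correlation`, `pathway_link`,
#'   `shared_metabolite_pairs`).
#' @export
generate_paired_dataset <- function(cfg) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  .validate_synth_config(cfg)
  set.seed(cfg$seed)

  otu_ids <- sprintf("OTU_%04d", seq_len(cfg$n_otus))
  taxonomy <- .random_taxonomy(otu_ids)

  # basis log-abundance model: heterogeneous means, guild block correlation
  mu <- stats::rnorm(cfg$n_otus, 0, 1.5)
  names(mu) <- otu_ids
  guild <- rep(NA_integer_, cfg$n_otus)
  names(guild) <- otu_ids
  if (cfg$n_guilds > 0 && cfg$guild_size > 0) {
    abundant <- order(mu, decreasing = TRUE)[seq_len(max(cfg$n_otus %/% 2,
                                                         cfg$n_guilds * cfg$guild_size))]
    picks <- sample(abundant, cfg$n_guilds * cfg$guild_size)
    guild[picks] <- rep(seq_len(cfg$n_guilds), each = cfg$guild_size)
  }
  sigma <- diag(cfg$n_otus)
  dimnames(sigma) <- list(otu_ids, otu_ids)
  for (g in seq_len(cfg$n_guilds)) {
    idx <- which(guild == g)
    sigma[idx, idx] <- cfg$guild_corr
    diag(sigma)[idx] <- 1
  }
  chol_sigma <- chol(sigma)

  # metabolite identities, module membership, masses and retention times
  met_ids <- sprintf("MET_%04d", seq_len(cfg$n_metabolites))
  module_sizes <- if (cfg$n_modules > 0) {
    round(seq(cfg$module_size_range[1], cfg$module_size_range[2],
              length.out = cfg$n_modules))
  } else integer(0)
  module_of <- rep("unclustered", cfg$n_metabolites)
  names(module_of) <- met_ids
  pos <- 1L
  for (m in seq_along(module_sizes)) {
    module_of[pos:(pos + module_sizes[m] - 1L)] <- sprintf("module_%d", m)
    pos <- pos + module_sizes[m]
  }

  # planted links: abundant non-guild-free OTUs, distinct unclustered metabolites
  uncl <- names(module_of)[module_of == "unclustered"]
  if (cfg$n_planted_links > length(uncl))
    stop("invalid synth_config: n_planted_links exceeds unclustered metabolites")
  eligible_otus <- otu_ids[order(mu, decreasing = TRUE)[seq_len(cfg$n_otus %/% 2)]]
  link_otus <- sample(eligible_otus, cfg$n_planted_links,
                      replace = cfg$n_planted_links > length(eligible_otus))
  link_mets <- sample(uncl, cfg$n_planted_links)
  n_neg <- round(cfg$frac_negative_links * cfg$n_planted_links)
  link_sign <- rep(1L, cfg$n_planted_links)
  if (n_neg > 0) link_sign[sample(cfg$n_planted_links, n_neg)] <- -1L
  link_list <- data.frame(otu_id = link_otus, metabolite_id = link_mets,
                          sign = link_sign, stringsAsFactors = FALSE)

  # masses on a 0.02-grid with sub-grid offsets: distinct identities always
  # separated by > 0.01 m/z before measurement jitter
  grid <- seq(60, 800, by = 0.02)
  mass <- sort(sample(grid, cfg$n_metabolites)) +
    stats::runif(cfg$n_metabolites, -0.002, 0.002)
  rt <- stats::runif(cfg$n_metabolites, 0.3, 9.5)
  mode <- sample(c("ESI+", "ESI-"), cfg$n_metabolites, replace = TRUE)

  # shared identities: module members and link metabolites first, then fill
  n_shared <- round(cfg$shared_metabolite_fraction * cfg$n_metabolites)
  must_share <- union(names(module_of)[module_of != "unclustered"], link_mets)
  n_shared <- max(n_shared, length(must_share))
  extra <- setdiff(met_ids, must_share)
  shared_ids <- c(must_share, sample(extra, n_shared - length(must_share)))
  shared <- met_ids %in% shared_ids

  # pathways: one linked pathway per planted-link metabolite
  pw_ids <- sprintf("ko%05d", seq_len(cfg$n_pathways))
  link_pw <- pw_ids[((seq_len(cfg$n_planted_links) - 1L) %% cfg$n_pathways) + 1L]
  pathway_link <- data.frame(metabolite_id = link_mets, pathway_id = link_pw,
                             stringsAsFactors = FALSE)

  tree <- ape::rphylo(cfg$n_otus, birth = 1, death = 0)
  tree$tip.label <- sample(otu_ids)

  a <- .spearman_to_pearson(cfg$link_effect)

  draw_region <- function(region, region_tag) {
    n <- cfg$n_subjects
    samples <- sprintf("%s_S%02d", region_tag, seq_len(n))
    depths <- stats::rpois(n, cfg$read_depth_mean)
    eps <- matrix(stats::rnorm(n * cfg$n_otus), n) %*% chol_sigma
    logab <- sweep(eps, 2, mu, "+")
    p <- exp(logab)
    p <- p / rowSums(p)
    counts <- t(vapply(seq_len(n),
                       function(i) stats::rmultinom(1, depths[i], p[i, ])[, 1],
                       numeric(cfg$n_otus)))
    dimnames(counts) <- list(samples, otu_ids)
    relab <- counts / pmax(rowSums(counts), 1)

    # metabolite log-intensities
    factors <- matrix(stats::rnorm(n * max(cfg$n_modules, 1)), n)
    colnames(factors) <- if (cfg$n_modules > 0)
      sprintf("module_%d", seq_len(cfg$n_modules)) else "module_0"
    z <- matrix(stats::rnorm(n * cfg$n_metabolites), n,
                dimnames = list(samples, met_ids))
    for (j in seq_len(cfg$n_metabolites)) {
      mo <- module_of[j]
      if (mo != "unclustered") {
        z[, j] <- sqrt(cfg$module_corr) * factors[, mo] +
          sqrt(1 - cfg$module_corr) * z[, j]
      }
    }
    for (l in seq_len(nrow(link_list))) {
      u <- .normal_scores(relab[, link_list$otu_id[l]])
      j <- link_list$metabolite_id[l]
      z[, j] <- link_list$sign[l] * a * u + sqrt(1 - a^2) * z[, j]
    }
    keep <- shared | (region == 1L)
    # region 2 replaces non-shared identities with its own unique features
    if (region == 2L) {
      n_uniq <- sum(!shared)
      uniq_mass <- sort(sample(setdiff(grid, round(mass / 0.02) * 0.02), n_uniq)) +
        stats::runif(n_uniq, -0.002, 0.002)
      uniq_rt <- stats::runif(n_uniq, 0.3, 9.5)
      uniq_mode <- sample(c("ESI+", "ESI-"), n_uniq, replace = TRUE)
    }
    feat_id <- sprintf("%s_%s", region_tag, met_ids)
    fmz <- mass
    frt <- rt
    fmode <- mode
    if (region == 2L) {
      jit_m <- stats::rnorm(cfg$n_metabolites, 0, cfg$mass_jitter_sd)
      jit_r <- stats::rnorm(cfg$n_metabolites, 0, cfg$rt_jitter_sd)
      fmz <- mass + jit_m
      frt <- pmax(rt + jit_r, 0)
      fmz[!shared] <- uniq_mass
      frt[!shared] <- uniq_rt
      fmode[!shared] <- uniq_mode
      # non-shared region-2 features are fresh identities: replace intensity
      z[, !shared] <- stats::rnorm(n * sum(!shared))
    }
    intens <- exp(8 + 0.7 * z)
    colnames(intens) <- feat_id
    meta <- data.frame(feature_id = feat_id, mz = fmz, rt = frt, mode = fmode,
                       stringsAsFactors = FALSE)
    mets <- metabolite_table(intens, meta)

    # per-OTU pathway profile concordant with planted links
    pw <- matrix(exp(stats::rnorm(cfg$n_otus * cfg$n_pathways, 0, 0.4)),
                 cfg$n_otus, dimnames = list(otu_ids, pw_ids))
    for (l in seq_len(nrow(pathway_link))) {
      o <- link_list$otu_id[l]
      expected_rho <- link_list$sign[l] * a * sigma[, o]
      pw[, pathway_link$pathway_id[l]] <- pw[, pathway_link$pathway_id[l]] *
        exp(2.5 * expected_rho)
    }
    list(otu = otu_table(counts, taxonomy),
         metabolites = mets,
         pathways = pathway_profile(pw),
         tree = tree,
         region = region_tag,
         module_factors = factors[, seq_len(cfg$n_modules), drop = FALSE])
  }

  b1 <- draw_region(1L, "R1")
  b2 <- draw_region(2L, "R2")

  shared_pairs <- data.frame(
    feature_region1 = sprintf("R1_%s", met_ids[shared]),
    feature_region2 = sprintf("R2_%s", met_ids[shared]),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    link_list = link_list,
    module_assignment = module_of,
    module_factors = list(region1 = b1$module_factors,
                          region2 = b2$module_factors),
    guild_assignment = guild,
    basis_correlation = sigma,
    pathway_link = pathway_link,
    shared_metabolite_pairs = shared_pairs), class = "ground_truth")

  b1$module_factors <- NULL
  b2$module_factors <- NULL
  class(b1) <- class(b2) <- "dataset_bundle"
  list(region1 = b1, region2 = b2, truth = truth)
}

# taxonomy strings over >= 5 phyla with realistic gut phylum frequencies
.random_taxonomy <- function(otu_ids) {
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Actinobacteria", "Tenericutes", "Verrucomicrobia")
  probs <- c(0.42, 0.40, 0.09, 0.05, 0.02, 0.02)
  genera <- list(
    Bacteroidetes = c("Bacteroides", "Prevotella", "Parabacteroides", "Alistipes"),
    Firmicutes = c("Clostridium", "Blautia", "Coprococcus", "Faecalibacterium",
                   "Roseburia", "Ruminococcus", "Oscillospira", "Lachnospira"),
    Proteobacteria = c("Ralstonia", "Sutterella", "Desulfovibrio", "Afipia"),
    Actinobacteria = c("Bifidobacterium", "Collinsella", "Actinomyces"),
    Tenericutes = c("Mycoplasma", "Anaeroplasma"),
    Verrucomicrobia = c("Akkermansia"))
  ph <- sample(phyla, length(otu_ids), replace = TRUE, prob = probs)
  # roughly half of OTUs carry genus-level resolution
  has_genus <- stats::runif(length(otu_ids)) < 0.6
  gen <- vapply(seq_along(otu_ids), function(i) {
    if (has_genus[i]) sample(genera[[ph[i]]], 1) else ""
  }, character(1))
  tax <- sprintf("k__Bacteria;p__%s;c__;o__;f__;g__%s;s__", ph, gen)
  names(tax) <- otu_ids
  tax
}

#' Simulate two coupled multivariate tables on the same samples
#'
#' Convenience generator for concordance power studies: a "microbiome-like"
#' table built from latent sample factors, and a "metabolome-like" table that
#' mixes the same factors in proportion `coupling` with independent noise.
#' At `coupling = 0` the tables are independent; as coupling grows, global
#' concordance statistics (Procrustes, RV) gain power.
#'
#' @param n_samples,p_features_x,p_features_y dimensions.
#' @param coupling value in \[0, 1\]: weight of the shared factors in `y`.
#' @param n_factors number of shared latent factors.
#' @param seed integer seed.
#' @return list with matrices `x` and `y` (samples in rows).
#' @export
simulate_coupled_tables <- function(n_samples, p_features_x, p_features_y,
                                    coupling, n_factors = 3L, seed = 1L) {
  stopifnot(coupling >= 0, coupling <= 1)
  set.seed(seed)
  f <- matrix(stats::rnorm(n_samples * n_factors), n_samples)
  ax <- matrix(stats::rnorm(n_factors * p_features_x), n_factors)
  ay <- matrix(stats::rnorm(n_factors * p_features_y), n_factors)
  x <- f %*% ax + matrix(stats::rnorm(n_samples * p_features_x), n_samples)
  y <- coupling * (f %*% ay) +
    sqrt(max(1 - coupling^2, 0)) *
    matrix(stats::rnorm(n_samples * p_features_y), n_samples)
  rownames(x) <- rownames(y) <- sprintf("S%03d", seq_len(n_samples))
  colnames(x) <- sprintf("X%03d", seq_len(p_features_x))
  colnames(y) <- sprintf("Y%03d", seq_len(p_features_y))
  list(x = x, y = y)
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits the same on-disk formats the readers accept: a classic tab-delimited
#' OTU table, a metabolite feature table, a pathway profile table and a
#' newick tree, plus (optionally) tab-delimited ground-truth files for test
#' harnesses.
#'
#' @param bundle a `dataset_bundle` from [generate_paired_dataset()].
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth` to write alongside.
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset_bundle <- function(bundle, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    otu = file.path(dir, "otu_table.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    tree = file.path(dir, "tree.nwk"))
  write_otu_table(bundle$otu, paths["otu"])
  write_metabolite_table(bundle$metabolites, paths["metabolites"])
  write_pathway_profile(bundle$pathways, paths["pathways"])
  ape::write.tree(bundle$tree, paths["tree"])
  if (!is.null(truth)) {
    tp <- file.path(dir, c("truth_links.tsv", "truth_modules.tsv",
                           "truth_guilds.tsv", "truth_pathway_links.tsv",
                           "truth_shared_metabolites.tsv"))
    utils::write.table(truth$link_list, tp[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(metabolite_id = names(truth$module_assignment),
                 module = unname(truth$module_assignment)),
      tp[2], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(otu_id = names(truth$guild_assignment),
                 guild = unname(truth$guild_assignment)),
      tp[3], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$pathway_link, tp[4], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth$shared_metabolite_pairs, tp[5], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}
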