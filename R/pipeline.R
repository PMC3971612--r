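#' Pipeline configuration
#'
#' Collects input paths and every stage parameter, with the analysis
#' defaults used throughout the package: rarefaction depth 30,000 reads,
#' 18% above-background prevalence, q < 0.2 edge significance, minimum
#' module size 10, 1,000 community permutations with +/-0.2 thresholds,
#' 20 ppm identification window and 0.005 m/z / 0.04 min cross-region
#' match tolerances.
#'
#' @param region1 named list with paths `otu`, `metabolites`, and optionally
#'   `pathways`, `tree` (as written by [write_dataset_bundle()]).
#' @param region2 optional second-region list of the same shape; enables
#'   cross-region metabolite matching and cluster overlap.
#' @param out_dir output directory for stage tables and the manifest.
#' @param seed master seed; per-stage seeds are spawned from it
#'   deterministically.
#' @param rarefy_depth rarefaction depth, or `"auto"` for the smallest
#'   sample total (so no sample is dropped).
#' @param prevalence minimum above-background prevalence fraction.
#' @param min_detect_samples minimum samples with detection for OTUs.
#' @param q_max edge significance threshold.
#' @param soft_power `"auto"` or integer soft-thresholding power.
#' @param min_module_size minimum metabolite module size.
#' @param k number of OTU clusters, or `"auto"` (prediction strength).
#' @param k_range candidate cluster numbers for prediction strength.
#' @param n_perm_concordance permutations for Procrustes/RV tests.
#' @param n_perm_community permutations for community-structure tests.
#' @param community_thresholds supplementary correlation count thresholds.
#' @param min_community_otus smallest metabolite-associated OTU group
#'   tested for community structure.
#' @param max_community_groups cap on the number of groups tested.
#' @param n_dirichlet SparCC Dirichlet draws.
#' @param ppm identification mass window (ppm).
#' @param max_dmass,max_drt cross-region match tolerances.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(region1, region2 = NULL, out_dir = "syntropy_out",
                            seed = 1L, rarefy_depth = 30000,
                            prevalence = 0.18, min_detect_samples = 2L,
                            q_max = 0.2, soft_power = "auto",
                            min_module_size = 10L, k = "auto",
                            k_range = 2:6, n_perm_concordance = 999L,
                            n_perm_community = 1000L,
                            community_thresholds = c(0.2, -0.2),
                            min_community_otus = 8L,
                            max_community_groups = 3L, n_dirichlet = 20L,
                            ppm = 20, max_dmass = 0.005, max_drt = 0.04) {
  cfg <- as.list(environment())
  stopifnot(is.list(region1), !is.null(region1$otu), !is.null(region1$metabolites))
  structure(cfg, class = "pipeline_config")
}

#' Run the full integrative analysis pipeline
#'
#' Executes the stages in order for each region -- preprocess (rarefaction
#' and prevalence/detection filters), metabolite modules, module/unclustered
#' combination, inter-omic Spearman network with q-values, global
#' concordance (PCA + Procrustes + coinertia RV), metabolite-driven OTU
#' clustering, pathway differentiation tests, community-structure
#' permutation tests, and putative identification -- then, when a second
#' region is configured, cross-region metabolite matching and cluster
#' overlap. Every output table is tab-delimited; the manifest lists each
#' file with its MD5 content hash, and a rerun with the same configuration
#' and seed reproduces identical hashes. A stage failure aborts with the
#' stage name and cause; outputs of completed stages are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `results` (per-region result objects) and
#'   `manifest` (data.frame of file, md5).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 16)
  files <- character(0)
  results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  emit <- function(path) files <<- c(files, path)

  analyse_region <- function(paths, tag, seed_offset) {
    out <- function(name) file.path(cfg$out_dir, sprintf("%s_%s", tag, name))
    res <- list()

    # --- preprocess ---------------------------------------------------
    res$otu <- stage("preprocess", {
      otu <- read_otu_table(paths$otu)
      depth <- if (identical(cfg$rarefy_depth, "auto"))
        min(rowSums(otu$counts)) else cfg$rarefy_depth
      otu <- rarefy(otu, depth = depth, seed = stage_seeds[1] + seed_offset)
      otu <- filter_min_samples(otu, cfg$min_detect_samples)
      otu <- filter_prevalence(otu, cfg$prevalence)
      emit(write_otu_table(otu, out("otu_filtered.tsv")))
      otu
    })
    res$mets <- stage("preprocess", {
      mets <- read_metabolite_table(paths$metabolites)
      mets <- filter_prevalence(mets, cfg$prevalence)
      emit(write_metabolite_table(mets, out("metabolites_filtered.tsv")))
      mets
    })
    shared <- intersect(rownames(res$otu$counts), rownames(res$mets$intensities))
    res$relab <- sweep(res$otu$counts[shared, , drop = FALSE], 1,
                       pmax(rowSums(res$otu$counts[shared, , drop = FALSE]), 1), "/")
    # log-intensities for correlation-based stages (MS intensities are
    # right-skewed; log1p when zeros are present)
    met_mat <- res$mets$intensities[shared, , drop = FALSE]
    met_log <- if (any(met_mat <= 0)) log1p(met_mat) else log(met_mat)

    # --- metabolite modules -------------------------------------------
    res$modules <- stage("modules", {
      ms <- metabolite_modules(met_log, power = cfg$soft_power,
                               min_size = cfg$min_module_size)
      emit(write_module_assignment(ms, res$mets, out("modules.tsv")))
      ms
    })
    res$analytes <- stage("combine", {
      combine_with_unclustered(res$modules, met_log)
    })

    # --- inter-omic network -------------------------------------------
    res$net <- stage("network",
                     spearman_all_pairs(res$relab, res$analytes,
                                        seed = stage_seeds[7] + seed_offset))
    res$sig <- significant_edges(res$net, cfg$q_max)
    emit(write_edge_list(res$sig, out("edges_significant.tsv")))
    res$summary <- summarize_network(res$sig, res$otu)
    res$genus <- bin_by_genus(res$sig, res$otu$taxonomy, res$otu)
    stage("network", {
      utils::write.table(res$genus, out("genus_interactions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(out("genus_interactions.tsv"))
    })

    # --- global concordance -------------------------------------------
    res$concordance <- stage("concordance", {
      pc_x <- pca_euclidean(res$relab)
      pc_y <- pca_euclidean(res$analytes)
      pro <- procrustes_test(pc_x, pc_y, n_perm = cfg$n_perm_concordance,
                             seed = stage_seeds[2] + seed_offset)
      rv <- coinertia_rv(res$relab, res$analytes,
                         n_perm = cfg$n_perm_concordance,
                         seed = stage_seeds[3] + seed_offset)
      df <- data.frame(statistic = c("procrustes_m12_sq", "rv"),
                       value = c(pro$statistic, rv$statistic),
                       p_value = c(pro$p_value, rv$p_value))
      utils::write.table(df, out("concordance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(out("concordance.tsv"))
      list(procrustes = pro, rv = rv)
    })

    # --- metabolite-driven OTU clusters --------------------------------
    res$clusters <- stage("clusters", {
      profiles <- correlation_profile_matrix(res$net, cfg$q_max)
      k <- cfg$k
      ps <- NULL
      if (identical(k, "auto")) {
        ps <- prediction_strength(profiles,
                                  k_range = cfg$k_range[cfg$k_range * 2 <= nrow(profiles)],
                                  n_splits = 20L,
                                  seed = stage_seeds[4] + seed_offset)
        k <- ps$k_star
      }
      ca <- cluster_otus(profiles, k)
      emit(write_cluster_assignment(ca, res$otu$taxonomy, out("clusters.tsv")))
      list(assignment = ca, prediction = ps, profiles = profiles)
    })

    # --- pathway differentiation --------------------------------------
    if (!is.null(paths$pathways)) {
      res$pathway_tests <- stage("function", {
        pp <- read_pathway_profile(paths$pathways)
        keep <- intersect(names(res$clusters$assignment$cluster),
                          rownames(pp$abundance))
        ca <- res$clusters$assignment
        ca$cluster <- ca$cluster[keep]
        pt <- cluster_pathway_tests(pp, ca)
        utils::write.table(pt, out("pathway_tests.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(out("pathway_tests.tsv"))
        pt
      })
    }

    # --- community structure ------------------------------------------
    res$community <- stage("community", {
      present6 <- filter_min_samples(res$otu, 6L)
      edge_counts <- table(res$sig$analyte_id)
      groups <- names(sort(edge_counts[edge_counts >= cfg$min_community_otus],
                           decreasing = TRUE))
      groups <- utils::head(groups, cfg$max_community_groups)
      tree <- if (!is.null(paths$tree)) ape::read.tree(paths$tree) else NULL
      fit <- if (length(groups) > 0) {
        set.seed(stage_seeds[6] + seed_offset)
        .sparcc_run(present6$counts, cfg$n_dirichlet, 10L, 0.1)
      }
      out_rows <- lapply(seq_along(groups), function(i) {
        g <- groups[i]
        otus <- intersect(res$sig$otu_id[res$sig$analyte_id == g],
                          colnames(present6$counts))
        if (length(otus) < 4) return(NULL)
        gs <- group_structure_test(present6, otus,
                                   n_perm = cfg$n_perm_community,
                                   thresholds = cfg$community_thresholds,
                                   seed = stage_seeds[5] + seed_offset + i,
                                   n_dirichlet = cfg$n_dirichlet,
                                   sparcc_fit = fit,
                                   group_id = g)
        gs_row <- data.frame(
          group = g, n_otus = gs$n_otus,
          total_branch_length = if (!is.null(tree))
            total_branch_length(tree, intersect(otus, tree$tip.label)) else NA,
          association_type = association_type(
            res$sig$rho[res$sig$analyte_id == g & res$sig$otu_id %in% otus]),
          mean_pos = gs$mean_pos, mean_neg = gs$mean_neg,
          n_above = gs$n_above, n_below = gs$n_below,
          p_mean_pos = gs$p_mean_pos, p_mean_neg = gs$p_mean_neg,
          p_above = gs$p_above, p_below = gs$p_below,
          stringsAsFactors = FALSE)
        list(result = gs, row = gs_row)
      })
      out_rows <- Filter(Negate(is.null), out_rows)
      tab <- do.call(rbind, lapply(out_rows, `[[`, "row"))
      if (!is.null(tab)) {
        utils::write.table(tab, out("community_structure.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(out("community_structure.tsv"))
      }
      lapply(out_rows, `[[`, "result")
    })

    # --- putative identification --------------------------------------
    res$ids <- stage("identify", {
      db <- read_compound_db()
      sig_feats <- intersect(unique(res$sig$analyte_id),
                             res$mets$feature_meta$feature_id)
      meta <- res$mets$feature_meta
      rows <- lapply(sig_feats, function(f) {
        m <- meta[meta$feature_id == f, ]
        if (m$mz < 50 || m$mz > 850) return(NULL)
        hits <- putative_ids(m$mz, m$mode, db, ppm = cfg$ppm)
        if (nrow(hits) == 0) return(NULL)
        cbind(feature_id = f, hits)
      })
      ids <- do.call(rbind, Filter(Negate(is.null), rows))
      if (!is.null(ids)) {
        utils::write.table(ids, out("putative_ids.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        emit(out("putative_ids.tsv"))
      }
      ids
    })
    res
  }

  results$region1 <- analyse_region(cfg$region1, "region1", 0L)
  if (!is.null(cfg$region2)) {
    results$region2 <- analyse_region(cfg$region2, "region2", 100L)

    results$match <- stage("match", {
      mm <- match_across_regions(results$region1$mets, results$region2$mets,
                                 max_dmass = cfg$max_dmass,
                                 max_drt = cfg$max_drt)
      p <- file.path(cfg$out_dir, "metabolite_matches.tsv")
      utils::write.table(mm$pairs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(p)
      mm
    })
    results$overlap <- stage("overlap", {
      ov <- cross_region_overlap(results$region1$clusters$assignment,
                                 results$region2$clusters$assignment)
      p <- file.path(cfg$out_dir, "cluster_overlap.tsv")
      utils::write.table(ov, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
      ov
    })
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(results = results, manifest = manifest))
}
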