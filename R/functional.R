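#' Single-count OTU table for external metagenome imputation
#'
#' The input convention for imputing a metagenome per OTU with external
#' tools: a synthetic OTU x OTU table in which each OTU is represented by a
#' single count in its own column (an identity count matrix). Internally the
#' pipeline consumes any [pathway_profile()]; this helper only emits the
#' convention for users who run the imputation themselves.
#'
#' @param otu_ids character vector of OTU identifiers.
#' @param tax optional taxonomy (defaults to empty strings).
#' @return An [otu_table()] whose count matrix is the identity.
#' @export
single_count_profile_convention <- function(otu_ids, tax = NULL) {
  if (length(otu_ids) == 0) stop("need a nonempty OTU list")
  counts <- diag(length(otu_ids))
  dimnames(counts) <- list(otu_ids, otu_ids)
  if (is.null(tax)) tax <- stats::setNames(rep("", length(otu_ids)), otu_ids)
  otu_table(counts, tax)
}

#' Kruskal-Wallis tests of pathway differentiation across OTU clusters
#'
#' For each pathway, tests whether its per-OTU imputed abundance differs
#' across the microbial clusters (tie-corrected Kruskal-Wallis H), with
#' Bonferroni correction over pathways. Each cluster's direction (enriched
#' or depleted) is read off its mean rank relative to the overall mean rank.
#' Clusters with fewer than 2 OTUs are excluded with a warning.
#'
#' @param pp a [pathway_profile()] covering every clustered OTU.
#' @param ca a `cluster_assignment`.
#' @return data.frame with one row per pathway: `pathway_id`, `H`, `df`,
#'   `p`, `p_bonferroni`, `significant` (Bonferroni P < 0.05), and one
#'   `direction_cluster_<i>` column per cluster (+1 enriched / -1 depleted).
#' @export
cluster_pathway_tests <- function(pp, ca) {
  ab <- pp$abundance
  cl <- ca$cluster[intersect(names(ca$cluster), rownames(ab))]
  if (length(cl) < length(ca$cluster))
    stop("every clustered OTU needs a pathway row; missing: ",
         paste(setdiff(names(ca$cluster), rownames(ab)), collapse = ", "))
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < 2])
  if (length(small) > 0) {
    warning(sprintf("excluding cluster(s) with < 2 OTUs: %s",
                    paste(small, collapse = ", ")))
    cl <- cl[!cl %in% small]
  }
  ab <- ab[names(cl), , drop = FALSE]
  groups <- factor(cl)
  k <- nlevels(groups)
  res <- lapply(colnames(ab), function(pw) {
    v <- ab[, pw]
    if (length(unique(v)) == 1) {
      h <- 0; p <- 1  # tie-corrected H of identical values
    } else {
      kt <- stats::kruskal.test(v, groups)
      h <- unname(kt$statistic); p <- kt$p.value
    }
    r <- rank(v)
    dirs <- vapply(levels(groups),
                   function(g) sign(mean(r[groups == g]) - mean(r)), numeric(1))
    c(H = h, p = p, dirs)
  })
  mat <- do.call(rbind, res)
  out <- data.frame(pathway_id = colnames(ab), H = mat[, "H"], df = k - 1L,
                    p = mat[, "p"], stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$significant <- out$p_bonferroni < 0.05
  dir_cols <- mat[, -(1:2), drop = FALSE]
  colnames(dir_cols) <- sprintf("direction_cluster_%s", levels(groups))
  rownames(out) <- NULL
  cbind(out, dir_cols)
}

#' Concordance of metabolite correlations with imputed pathway abundance
#'
#' For each metabolite carrying at least `min_otus` significant OTU edges
#' and at least one putative (compound, pathway) identification: vector A is
#' the metabolite's Spearman rho against *every* OTU in the analysis
#' universe (raw, unthresholded); vector B is the candidate pathway's
#' imputed abundance in every OTU. The two vectors are aligned by OTU and
#' compared with Pearson correlation; p-values are Bonferroni-corrected over
#' all tested (metabolite, pathway) records, and each record is categorised
#' as `positive`, `negative` or `not_significant` by the corrected p (< 0.05)
#' and the sign of r. OTUs with undefined rho are dropped pairwise; records
#' whose candidate pathway is absent from the profile are skipped with a
#' warning.
#'
#' @param net an `interomic_network` from [spearman_all_pairs()] (full
#'   network; significance is assessed internally at `q_max`).
#' @param pp a [pathway_profile()].
#' @param id_map data.frame with columns `metabolite_id`, `compound`,
#'   `pathway_id`: the putative identification candidates per metabolite.
#' @param min_otus minimum number of significant OTU edges (inclusive,
#'   default 5).
#' @param q_max edge significance threshold (default 0.2).
#' @return data.frame of concordance records: `metabolite_id`,
#'   `putative_compound`, `pathway_id`, `n_otus`, `pearson_r`, `p`,
#'   `p_bonferroni`, `category`.
#' @export
metabolite_metagenome_concordance <- function(net, pp, id_map, min_otus = 5L,
                                              q_max = 0.2) {
  rho <- attr(net, "rho_matrix")
  if (is.null(rho)) stop("network lacks the full rho matrix")
  sig <- net[net$q < q_max, , drop = FALSE]
  n_sig <- table(factor(sig$analyte_id, levels = colnames(rho)))
  eligible <- names(n_sig)[n_sig >= min_otus]
  cand <- id_map[id_map$metabolite_id %in% eligible, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(metabolite_id = character(0),
                      putative_compound = character(0),
                      pathway_id = character(0), n_otus = integer(0),
                      pearson_r = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  missing_pw <- !(cand$pathway_id %in% colnames(pp$abundance))
  if (any(missing_pw)) {
    warning(sprintf("skipping %d record(s) with pathway absent from profile: %s",
                    sum(missing_pw),
                    paste(unique(cand$pathway_id[missing_pw]), collapse = ", ")))
    cand <- cand[!missing_pw, , drop = FALSE]
  }
  otus <- intersect(rownames(rho), rownames(pp$abundance))
  res <- lapply(seq_len(nrow(cand)), function(i) {
    met <- cand$metabolite_id[i]
    a <- rho[otus, met]
    b <- pp$abundance[otus, cand$pathway_id[i]]
    ok <- !is.na(a)
    ct <- stats::cor.test(a[ok], b[ok])
    data.frame(metabolite_id = met, putative_compound = cand$compound[i],
               pathway_id = cand$pathway_id[i], n_otus = sum(ok),
               pearson_r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$category <- ifelse(out$p_bonferroni < 0.05,
                         ifelse(out$pearson_r > 0, "positive", "negative"),
                         "not_significant")
  rownames(out) <- NULL
  out
}
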