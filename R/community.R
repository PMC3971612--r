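#' Permutation test of metabolite-associated community structure
#'
#' Runs SparCC on the count submatrix of a group of OTUs (e.g. all OTUs
#' significantly correlated with one metabolite or module) and summarises
#' its correlation matrix by the mean positive correlation, mean negative
#' correlation, and the numbers of correlations above `thresholds[1]` and
#' below `thresholds[2]`. The null distribution comes from `n_perm` random
#' OTU sets of the same size drawn without replacement from the full
#' (prevalence-thresholded) table; each p-value is the add-one-corrected
#' fraction of permutations with a *stronger* statistic than observed
#' (larger mean positive, more negative mean negative, larger counts).
#'
#' @param counts the full [otu_table()] (or matrix) the null sets are drawn
#'   from; the caller is expected to have applied the presence filter (e.g.
#'   detected in at least six samples) beforehand.
#' @param group character vector of OTU ids, all present in `counts`,
#'   with at least 4 members.
#' @param n_perm number of permutations (default 1000).
#' @param thresholds numeric pair `(upper, lower)` for the supplementary
#'   counts (default `c(0.2, -0.2)`).
#' @param seed integer seed.
#' @param n_dirichlet,n_exclusion_iters,exclusion_threshold passed to the
#'   SparCC estimator.
#' @param ordered_pairs logical; count ordered pairs (both triangles of the
#'   symmetric matrix, giving even counts) rather than unordered pairs.
#' @param scope `"full"` (default) estimates SparCC once on the whole table
#'   -- where the sparsity assumption holds -- and reads each group's
#'   statistics off the corresponding submatrix of that estimate;
#'   `"subtable"` re-runs SparCC on each group's count submatrix. The full
#'   scope is the default because a group whose members co-vary through a
#'   shared factor leaves no trace in its own internal log-ratios (the
#'   factor cancels), so submatrix-only estimation cannot detect exactly
#'   the cooperative structure the test targets.
#' @param sparcc_fit optional precomputed `sparcc_result` for the full
#'   table (used with `scope = "full"` to avoid re-estimation).
#' @return list of class `community_structure_result` with `group_id`,
#'   `n_otus`, `mean_pos`, `mean_neg`, `n_above`, `n_below`, and permutation
#'   p-values `p_mean_pos`, `p_mean_neg`, `p_above`, `p_below` (each in
#'   (0, 1\], never 0), plus `n_permutations`.
#' @export
group_structure_test <- function(counts, group, n_perm = 1000L,
                                 thresholds = c(0.2, -0.2), seed = 1L,
                                 n_dirichlet = 20L, n_exclusion_iters = 10L,
                                 exclusion_threshold = 0.1,
                                 ordered_pairs = TRUE,
                                 scope = c("full", "subtable"),
                                 sparcc_fit = NULL, group_id = NULL) {
  scope <- match.arg(scope)
  m <- .table_matrix(counts)
  if (length(group) < 4) stop("group must contain at least 4 OTUs")
  if (!all(group %in% colnames(m)))
    stop("group OTUs absent from table: ",
         paste(setdiff(group, colnames(m)), collapse = ", "))
  set.seed(seed)
  mult <- if (ordered_pairs) 2L else 1L
  if (scope == "full") {
    if (is.null(sparcc_fit))
      sparcc_fit <- .sparcc_run(m, n_dirichlet, n_exclusion_iters,
                                exclusion_threshold)
    full_rho <- sparcc_fit$correlation
    if (!all(group %in% rownames(full_rho)))
      stop("sparcc_fit does not cover all group OTUs")
  }
  stat <- function(ids) {
    r <- if (scope == "full") full_rho[ids, ids] else
      .sparcc_run(m[, ids, drop = FALSE], n_dirichlet, n_exclusion_iters,
                  exclusion_threshold)$correlation
    v <- r[upper.tri(r)]
    c(mean_pos = if (any(v > 0)) mean(v[v > 0]) else 0,
      mean_neg = if (any(v < 0)) mean(v[v < 0]) else 0,
      n_above = mult * sum(v > thresholds[1]),
      n_below = mult * sum(v < thresholds[2]))
  }
  obs <- stat(group)
  k <- length(group)
  stronger <- c(mean_pos = 0L, mean_neg = 0L, n_above = 0L, n_below = 0L)
  for (p in seq_len(n_perm)) {
    s <- stat(sample(colnames(m), k, replace = FALSE))
    stronger["mean_pos"] <- stronger["mean_pos"] + (s["mean_pos"] >= obs["mean_pos"])
    stronger["mean_neg"] <- stronger["mean_neg"] + (s["mean_neg"] <= obs["mean_neg"])
    stronger["n_above"] <- stronger["n_above"] + (s["n_above"] >= obs["n_above"])
    stronger["n_below"] <- stronger["n_below"] + (s["n_below"] >= obs["n_below"])
  }
  pv <- (1 + stronger) / (1 + n_perm)
  structure(list(group_id = if (is.null(group_id)) NA_character_ else group_id,
                 n_otus = as.integer(k),
                 mean_pos = unname(obs["mean_pos"]),
                 mean_neg = unname(obs["mean_neg"]),
                 n_above = as.integer(obs["n_above"]),
                 n_below = as.integer(obs["n_below"]),
                 p_mean_pos = unname(pv["mean_pos"]),
                 p_mean_neg = unname(pv["mean_neg"]),
                 p_above = unname(pv["n_above"]),
                 p_below = unname(pv["n_below"]),
                 n_permutations = as.integer(n_perm)),
            class = "community_structure_result")
}

#' @export
print.community_structure_result <- function(x, ...) {
  cat(sprintf(
    "community structure [%s]: %d OTUs, mean+ %.3f (p=%.3g), mean- %.3f (p=%.3g)\n",
    x$group_id, x$n_otus, x$mean_pos, x$p_mean_pos, x$mean_neg, x$p_mean_neg))
  cat(sprintf("  correlations > %.2g: %d (p=%.3g); < %.2g: %d (p=%.3g)\n",
              0.2, x$n_above, x$p_above, -0.2, x$n_below, x$p_below))
  invisible(x)
}

#' Label the sign pattern of a metabolite's edge set
#'
#' Classifies the signed correlations of a metabolite (or module) with its
#' OTUs: `"all positive"` / `"all negative"` when one sign holds throughout,
#' `"mostly positive"` / `"mostly negative"` when at least 80% share a
#' sign, and otherwise a literal percentage label such as
#' `"30% negative, 70% positive"` (an exact 50/50 split also gets the
#' percentage form).
#'
#' @param rhos nonempty numeric vector of signed correlations.
#' @return character label.
#' @export
association_type <- function(rhos) {
  if (length(rhos) == 0) stop("need a nonempty correlation list")
  pos <- sum(rhos > 0)
  neg <- sum(rhos < 0)
  tot <- pos + neg
  if (tot == 0) return("all zero")
  if (neg == 0) return("all positive")
  if (pos == 0) return("all negative")
  if (pos / tot >= 0.8) return("mostly positive")
  if (neg / tot >= 0.8) return("mostly negative")
  sprintf("%d%% negative, %d%% positive",
          round(100 * neg / tot), round(100 * pos / tot))
}

#' Total branch length of the subtree induced by a tip set
#'
#' Sum of branch lengths of the subtree spanned by the given tips, rooted
#' at their most recent common ancestor (the stem above the MRCA is
#' excluded). A single tip has zero induced branch length.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param tips character vector of tip labels, all present in the tree.
#' @return numeric total branch length.
#' @export
total_branch_length <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0)
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  if (length(tips) <= 1) return(0)
  sub <- ape::keep.tip(tree, tips)
  sum(sub$edge.length)
}

#' Write a community-structure summary table
#'
#' One row per tested metabolite group, in the shape of a per-group summary
#' table: group, putative id, region, OTU count, total branch length,
#' association type, the four statistics and their permutation p-values.
#'
#' @param results list of `community_structure_result` objects.
#' @param path output path.
#' @param meta optional data.frame with columns `group_id`, `putative_id`,
#'   `region`, `total_branch_length`, `association_type` merged in by group.
#' @export
write_community_structure <- function(results, path, meta = NULL) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(group = r$group_id, n_otus = r$n_otus,
               mean_pos = r$mean_pos, mean_neg = r$mean_neg,
               n_above = r$n_above, n_below = r$n_below,
               p_mean_pos = r$p_mean_pos, p_mean_neg = r$p_mean_neg,
               p_above = r$p_above, p_below = r$p_below,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(meta)) df <- merge(meta, df, by.x = "group_id", by.y = "group")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
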