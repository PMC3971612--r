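#' OTU x analyte correlation-profile matrix
#'
#' The clustering input: the full (unthresholded) Spearman rho matrix,
#' restricted to analytes carrying at least `min_significant_otus`
#' significant OTU edges in the thresholded network. Cells whose rho was
#' undefined (zero-variance pairs) are imputed as 0 so that Euclidean
#' clustering sees complete rows; the imputation count is recorded in the
#' `n_imputed` attribute.
#'
#' @param net_full an `interomic_network` from [spearman_all_pairs()] (its
#'   `rho_matrix` attribute supplies the raw correlations).
#' @param q_max significance threshold applied when counting an analyte's
#'   significant OTU edges (default 0.2).
#' @param min_significant_otus analyte inclusion threshold, inclusive
#'   (default 2: an analyte with exactly 2 significant edges qualifies).
#' @return OTU x analyte numeric matrix of raw rho values.
#' @export
correlation_profile_matrix <- function(net_full, q_max = 0.2,
                                       min_significant_otus = 2L) {
  rho <- attr(net_full, "rho_matrix")
  if (is.null(rho)) stop("network lacks the full rho matrix")
  sig <- net_full[net_full$q < q_max, , drop = FALSE]
  n_sig <- table(factor(sig$analyte_id, levels = colnames(rho)))
  keep <- names(n_sig)[n_sig >= min_significant_otus]
  if (length(keep) == 0)
    stop("no analyte has >= ", min_significant_otus, " significant OTU edges")
  out <- rho[, keep, drop = FALSE]
  n_imp <- sum(is.na(out))
  out[is.na(out)] <- 0
  attr(out, "n_imputed") <- n_imp
  out
}

#' Cluster OTUs by their metabolite-correlation profiles
#'
#' Complete-linkage hierarchical clustering of the Euclidean distances
#' between OTU correlation profiles, cut into exactly `k` groups. The cut
#' height is the minimal height yielding `k` branches; when tied merge
#' heights make `k` unattainable by a horizontal cut, the nearest coarser
#' partition is refined by splitting clusters at their internal merges (via
#' [stats::cutree()] with `k`), and a note is recorded.
#'
#' @param profiles OTU x analyte matrix from [correlation_profile_matrix()].
#' @param k requested number of clusters.
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (named integer 1..k), `k`, `dendrogram` (hclust), `cut_height` (NA when
#'   no single height yields `k`) and `note`.
#' @export
cluster_otus <- function(profiles, k) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) stop("k exceeds the number of OTUs")
  tree <- stats::hclust(stats::dist(profiles), method = "complete")
  if (k == 1L) {
    cl <- stats::setNames(rep(1L, nrow(profiles)), rownames(profiles))
    return(structure(list(cluster = cl, k = 1L, dendrogram = tree,
                          cut_height = max(tree$height), note = NULL),
                     class = "cluster_assignment"))
  }
  heights <- sort(unique(tree$height))
  cut_height <- NA_real_
  note <- NULL
  # number of clusters at a cut just below the i-th largest merge
  for (h in rev(heights)) {
    ncl <- length(unique(stats::cutree(tree, h = h - 1e-10)))
    if (ncl == k) { cut_height <- h - 1e-10; break }
    if (ncl > k) break
  }
  if (is.na(cut_height)) {
    note <- sprintf("no cut height yields %d clusters; refined by splitting at internal merges", k)
    message(note)
  }
  cl <- if (is.na(cut_height)) stats::cutree(tree, k = k) else
    stats::cutree(tree, h = cut_height)
  # relabel clusters 1..k in order of first appearance in the dendrogram
  ord <- unique(cl[tree$order])
  cl <- stats::setNames(match(cl, ord), names(cl))
  structure(list(cluster = cl, k = as.integer(k), dendrogram = tree,
                 cut_height = cut_height, note = note),
            class = "cluster_assignment")
}

#' Prediction strength for choosing the number of clusters
#'
#' Cross-validated co-membership stability: for each candidate `k`, the data
#' are repeatedly split into halves, both halves are clustered with k-means,
#' and each test observation is classified to its nearest training centroid.
#' The prediction strength `ps(k)` is the minimum over test clusters of the
#' proportion of same-test-cluster pairs that the training centroids also
#' co-assign, averaged over splits; `ps(1) = 1` by definition. The selected
#' `k_star` is the largest `k` with `ps(k) >= threshold`.
#'
#' @param profiles observation x feature matrix (rows are the objects being
#'   clustered, e.g. OTU correlation profiles).
#' @param k_range integer candidates (1 is implicit).
#' @param n_splits number of random 2-fold splits (default 50).
#' @param threshold selection threshold (default 0.8).
#' @param seed integer seed.
#' @return list with `k_star` and `ps_curve` (data.frame of k, ps).
#' @export
prediction_strength <- function(profiles, k_range = 2:6, n_splits = 50L,
                                threshold = 0.8, seed = 1L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2 * max(k_range)) stop("need at least 2*max(k_range) observations")
  set.seed(seed)
  ps <- stats::setNames(numeric(length(k_range)), k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    vals <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      test <- sort(sample.int(n, n %/% 2))
      train <- setdiff(seq_len(n), test)
      km_tr <- stats::kmeans(profiles[train, , drop = FALSE], k, nstart = 5)
      km_te <- stats::kmeans(profiles[test, , drop = FALSE], k, nstart = 5)
      # classify test points by nearest training centroid
      d2 <- as.matrix(stats::dist(rbind(km_tr$centers,
                                        profiles[test, , drop = FALSE])))
      d2 <- d2[-(1:k), 1:k, drop = FALSE]
      pred <- apply(d2, 1, which.min)
      per_cluster <- vapply(seq_len(k), function(cl) {
        members <- which(km_te$cluster == cl)
        if (length(members) < 2) return(NA_real_)
        pairs <- utils::combn(members, 2)
        mean(pred[pairs[1, ]] == pred[pairs[2, ]])
      }, numeric(1))
      vals[s] <- if (all(is.na(per_cluster))) NA else min(per_cluster, na.rm = TRUE)
    }
    ps[ki] <- mean(vals, na.rm = TRUE)
  }
  curve <- data.frame(k = c(1L, k_range), ps = c(1, as.numeric(ps)))
  ok <- curve$k[curve$ps >= threshold]
  list(k_star = max(ok), ps_curve = curve)
}

#' Phylum composition of each OTU cluster
#'
#' @param ca a `cluster_assignment`.
#' @param tax named taxonomy strings per OTU.
#' @return list (one element per cluster) of named phylum fraction vectors,
#'   each summing to 1 (OTUs with unresolved phylum count as `"unknown"`).
#' @export
cluster_composition <- function(ca, tax) {
  phylum <- .tax_rank(tax, "phylum")
  out <- lapply(sort(unique(ca$cluster)), function(cl) {
    members <- names(ca$cluster)[ca$cluster == cl]
    ph <- phylum[members]
    ph[is.na(ph)] <- "unknown"
    tab <- table(ph)
    as.numeric(tab / sum(tab)) -> fr
    stats::setNames(fr, names(tab))
  })
  names(out) <- sprintf("cluster_%d", sort(unique(ca$cluster)))
  out
}

# one-sided (greater) Fisher p for a 2x2 table: hypergeometric upper tail
.fisher_greater_p <- function(a, b, c, d) {
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Cross-region overlap of cluster assignments
#'
#' For every pair of clusters (one per region), counts the shared OTUs
#' assigned to both and tests enrichment with a one-sided (greater) Fisher
#' exact test on the 2x2 table over the shared OTU universe. Significance
#' flags use a Bonferroni correction over all k1 x k2 cells at P < 0.05.
#'
#' @param ca1,ca2 `cluster_assignment` objects from the two regions.
#' @param shared_otus optional character vector restricting the OTU
#'   universe (defaults to the OTUs clustered in both regions).
#' @return data.frame with columns `cluster1`, `cluster2`, `overlap`,
#'   `expected`, `p_value`, `p_bonferroni`, `significant`.
#' @export
cross_region_overlap <- function(ca1, ca2, shared_otus = NULL) {
  if (is.null(shared_otus))
    shared_otus <- intersect(names(ca1$cluster), names(ca2$cluster))
  if (length(shared_otus) == 0) stop("shared OTU universe is empty")
  c1 <- ca1$cluster[shared_otus]
  c2 <- ca2$cluster[shared_otus]
  grid <- expand.grid(cluster1 = sort(unique(c1)), cluster2 = sort(unique(c2)))
  n <- length(shared_otus)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    in1 <- c1 == grid$cluster1[i]
    in2 <- c2 == grid$cluster2[i]
    a <- sum(in1 & in2); b <- sum(in1 & !in2)
    cc <- sum(!in1 & in2); d <- sum(!in1 & !in2)
    data.frame(cluster1 = grid$cluster1[i], cluster2 = grid$cluster2[i],
               overlap = a, expected = sum(in1) * sum(in2) / n,
               p_value = .fisher_greater_p(a, b, cc, d))
  })
  out <- do.call(rbind, res)
  m <- nrow(out)
  out$p_bonferroni <- pmin(out$p_value * m, 1)
  out$significant <- out$p_bonferroni < 0.05
  out
}

#' Write a cluster assignment table
#'
#' Tab-delimited `(otu_id, taxonomy, cluster)`.
#'
#' @param ca a `cluster_assignment`.
#' @param tax taxonomy strings.
#' @param path output path.
#' @export
write_cluster_assignment <- function(ca, tax, path) {
  df <- data.frame(otu_id = names(ca$cluster),
                   taxonomy = unname(tax[names(ca$cluster)]),
                   cluster = unname(ca$cluster), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
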