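# Pooled permutation p-values for all-pairs Spearman screening. The sample
# labels of the (ranked) analyte table are permuted `n_null_perm` times and
# every null |rho| across all pairs is pooled into one reference
# distribution; each observed |rho| gets the add-one empirical two-sided p.
# Unlike the t or Edgeworth approximations -- whose far tails are off by
# large factors at these sample sizes -- the pooled null is calibrated by
# construction exactly where large-scale FDR screening reads it (p ~ alpha/m),
# with resolution ~1/(n_null_perm x #pairs). Ties are handled naturally
# because tied columns contribute their own tie patterns to the pool.
.spearman_p_pooled <- function(rx, ry, rho_ok, n_null_perm = 200L) {
  n <- nrow(rx)
  obs <- sort(abs(rho_ok))
  total <- 0
  exceed <- numeric(length(obs))
  for (w in seq_len(n_null_perm)) {
    nr <- suppressWarnings(stats::cor(rx, ry[sample.int(n), , drop = FALSE]))
    nr <- abs(nr[!is.na(nr)])
    total <- total + length(nr)
    # count of null values >= each observed |rho|
    exceed <- exceed + (length(nr) -
                          findInterval(obs - 1e-12, sort.int(nr)))
  }
  p_sorted <- (1 + exceed) / (1 + total)
  p_sorted[rank(abs(rho_ok), ties.method = "first")]
}

#' All-pairs Spearman correlation between OTUs and analytes
#'
#' Builds the inter-omic network: one edge per (OTU, analyte) pair with the
#' Spearman rank correlation (midranks for ties), a two-sided p-value, and a
#' Storey q-value. Tables are merged on their shared sample identifiers.
#' Spearman is used because it detects monotone relationships that Pearson
#' misses. For n >= 10 samples, p-values come from a pooled
#' sample-permutation null (the analyte table's rows are permuted
#' `n_null_perm` times and null |rho| values are pooled across all pairs),
#' which keeps the far tail calibrated at the p ~ alpha/m scale where
#' large correlation screens operate; below 10 samples the exact
#' per-pair permutation distribution (via [stats::cor.test()]) is used.
#' Pairs where either vector has zero variance have undefined rank
#' correlation and are excluded (the count is recorded in the
#' `n_excluded_pairs` attribute).
#'
#' @param otus an [otu_table()] or samples x OTU matrix (counts or relative
#'   abundances; Spearman is invariant to the choice).
#' @param analytes samples x analyte matrix or [metabolite_table()]; analyte
#'   columns may be metabolites or module eigenmetabolites.
#' @param n_null_perm number of row permutations pooled into the null
#'   (default 200; the pooled null then has `200 x #pairs` draws).
#' @param seed integer seed for the permutation null.
#' @return An object of class `interomic_network`: a data.frame with columns
#'   `otu_id`, `analyte_id`, `rho`, `p`, `q`, plus attributes `rho_matrix`
#'   (the full OTU x analyte rho matrix, `NA` for excluded pairs),
#'   `n_samples` and `n_excluded_pairs`.
#' @export
spearman_all_pairs <- function(otus, analytes, n_null_perm = 200L, seed = 1L) {
  xm <- .table_matrix(otus)
  ym <- .table_matrix(analytes)
  shared <- intersect(rownames(xm), rownames(ym))
  if (length(shared) < 4)
    stop("tables share fewer than 4 samples after merging")
  xm <- xm[shared, , drop = FALSE]
  ym <- ym[shared, , drop = FALSE]
  n <- length(shared)

  rx <- apply(xm, 2, rank)
  ry <- apply(ym, 2, rank)
  const_x <- apply(xm, 2, function(v) length(unique(v)) == 1)
  const_y <- apply(ym, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(rx, ry))
  rho[const_x, ] <- NA
  rho[, const_y] <- NA
  dimnames(rho) <- list(colnames(xm), colnames(ym))

  ok <- !is.na(rho)
  idx <- which(ok, arr.ind = TRUE)
  if (n >= 10) {
    set.seed(seed)
    p_ok <- .spearman_p_pooled(rx[, !const_x, drop = FALSE],
                               ry[, !const_y, drop = FALSE],
                               rho[ok], n_null_perm)
  } else {
    p_ok <- vapply(seq_len(nrow(idx)), function(k) {
      suppressWarnings(
        stats::cor.test(xm[, idx[k, 1]], ym[, idx[k, 2]],
                        method = "spearman", exact = TRUE)$p.value)
    }, numeric(1))
  }
  p_ok <- pmax(p_ok, .Machine$double.xmin)

  edges <- data.frame(
    otu_id = rownames(rho)[idx[, 1]],
    analyte_id = colnames(rho)[idx[, 2]],
    rho = rho[ok], p = p_ok, stringsAsFactors = FALSE)
  qv <- qvalues(edges$p)
  edges$q <- as.numeric(qv)
  n_excl <- sum(!ok)
  if (n_excl > 0)
    message(sprintf("excluded %d zero-variance pair(s) with undefined rho", n_excl))
  structure(edges, class = c("interomic_network", "data.frame"),
            rho_matrix = rho, n_samples = n, n_excluded_pairs = n_excl,
            pi0 = attr(qv, "pi0"))
}

#' Threshold an inter-omic network on q-value
#'
#' Keeps edges with `q` strictly below `q_max` (default 0.2, the threshold
#' used throughout the pipeline; an edge at exactly the threshold is
#' dropped).
#'
#' @param net an `interomic_network`.
#' @param q_max significance threshold.
#' @return The thresholded `interomic_network`; attributes are carried over.
#' @export
significant_edges <- function(net, q_max = 0.2) {
  stopifnot(inherits(net, "interomic_network"), !is.null(net$q))
  out <- net[net$q < q_max, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out)[c("names", "row.names", "class")],
                       attributes(net)[c("rho_matrix", "n_samples",
                                         "n_excluded_pairs", "pi0")])
  class(out) <- c("interomic_network", "data.frame")
  out
}

#' Bin significant inter-omic edges by genus
#'
#' Groups OTUs at the genus rank and counts, per genus, the number of unique
#' correlated metabolites: duplicate metabolite correlations within a genus
#' collapse to a single interaction, so even if every OTU of a genus
#' correlates with one metabolite it counts once. OTUs without genus-level
#' resolution (empty or bare `g__` entries) are excluded. When an OTU table
#' is supplied, the genus' average relative abundance (percent) is reported
#' alongside.
#'
#' @param net a significant `interomic_network` (already thresholded).
#' @param tax named character vector of taxonomy strings per OTU.
#' @param otus optional [otu_table()] used for average relative abundance.
#' @return data.frame with columns `genus`, `n_unique_metabolites` and
#'   (if `otus` given) `mean_abundance_pct`, sorted by interaction count.
#' @export
bin_by_genus <- function(net, tax, otus = NULL) {
  genus <- .tax_rank(tax, "genus")
  g <- genus[net$otu_id]
  keep <- !is.na(g)
  counts <- if (any(keep)) {
    tapply(net$analyte_id[keep], g[keep], function(a) length(unique(a)))
  } else {
    stats::setNames(integer(0), character(0))
  }
  out <- data.frame(genus = names(counts),
                    n_unique_metabolites = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (!is.null(otus)) {
    rel <- sweep(otus$counts, 1, pmax(rowSums(otus$counts), 1), "/")
    gall <- .tax_rank(otus$taxonomy, "genus")
    genus_ab <- tapply(colMeans(rel), gall, sum)
    out$mean_abundance_pct <- 100 * as.numeric(genus_ab[out$genus])
  }
  out[order(-out$n_unique_metabolites, out$genus), , drop = FALSE]
}

#' Summarise an inter-omic network
#'
#' Edge totals, unique node counts, mean edges per OTU and per analyte, and
#' the per-phylum ratio of detected OTUs carrying at least one significant
#' edge (the share of each phylum's detected OTUs with metabolic
#' correlations).
#'
#' @param net a significant `interomic_network`.
#' @param otus the [otu_table()] defining the detected-OTU universe.
#' @param tax optional taxonomy (defaults to the table's own).
#' @return list of class `network_summary` with `total_edges`,
#'   `unique_otu_nodes`, `unique_analyte_nodes`, `mean_edges_per_otu`,
#'   `mean_edges_per_analyte` and `per_phylum_ratio`.
#' @export
summarize_network <- function(net, otus, tax = NULL) {
  if (is.null(tax)) tax <- otus$taxonomy
  total <- nrow(net)
  n_otu <- length(unique(net$otu_id))
  n_ana <- length(unique(net$analyte_id))
  phylum <- .tax_rank(tax, "phylum")
  detected <- colnames(otus$counts)
  with_edge <- unique(net$otu_id)
  ratio <- vapply(sort(unique(phylum[detected])), function(ph) {
    members <- detected[!is.na(phylum[detected]) & phylum[detected] == ph]
    if (length(members) == 0) return(0)
    sum(members %in% with_edge) / length(members)
  }, numeric(1))
  structure(list(
    total_edges = total,
    unique_otu_nodes = n_otu,
    unique_analyte_nodes = n_ana,
    mean_edges_per_otu = if (n_otu > 0) total / n_otu else 0,
    mean_edges_per_analyte = if (n_ana > 0) total / n_ana else 0,
    per_phylum_ratio = ratio), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("interomic network: %d edges, %d OTU nodes, %d analyte nodes\n",
              x$total_edges, x$unique_otu_nodes, x$unique_analyte_nodes))
  cat(sprintf("mean edges per OTU %.2f, per analyte %.2f\n",
              x$mean_edges_per_otu, x$mean_edges_per_analyte))
  for (ph in names(x$per_phylum_ratio))
    cat(sprintf("  %s: %.0f%% of detected OTUs have edges\n",
                ph, 100 * x$per_phylum_ratio[ph]))
  invisible(x)
}

#' Write an inter-omic edge list
#'
#' Tab-delimited `(otu_id, analyte_id, rho, p, q)`.
#'
#' @param net an `interomic_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(as.data.frame(net)[, c("otu_id", "analyte_id", "rho", "p", "q")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
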