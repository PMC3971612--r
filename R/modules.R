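#' Pick the soft-thresholding power for the metabolite co-occurrence network
#'
#' For each candidate power beta, forms the unsigned adjacency
#' `a_ij = |Pearson(x_i, x_j)|^beta` (zero diagonal) and measures how well
#' the connectivity distribution `k_i = sum_j a_ij` follows a power law:
#' connectivities are binned, and the scale-free fit index is the R-squared
#' of the regression of `log10 p(k)` on `log10 k` over the non-empty bins,
#' signed so that increasing frequency with connectivity (positive slope)
#' scores zero. Returns the smallest beta whose index reaches `r2_target`,
#' or failing that the beta maximising it.
#'
#' @param x samples x metabolite matrix (constant columns are excluded with
#'   a warning).
#' @param candidate_powers integer candidates; the default grid includes the
#'   commonly needed high powers 22 and 32.
#' @param r2_target scale-free fit target (default 0.8).
#' @param n_bins number of connectivity bins.
#' @return list with `power` (chosen beta) and `fit_table` (data.frame of
#'   beta, scale-free `r_squared`, `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(x,
                                candidate_powers = c(1:10, 12, 14, 16, 18,
                                                     20, 22, 26, 32),
                                r2_target = 0.8, n_bins = 10L) {
  x <- .table_matrix(x)
  if (ncol(x) < 10) stop("need at least 10 metabolites")
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("excluding %d constant metabolite column(s)", sum(const)))
    x <- x[, !const, drop = FALSE]
  }
  ac <- abs(stats::cor(x))
  diag(ac) <- 0
  fit <- lapply(candidate_powers, function(beta) {
    a <- ac^beta
    k <- rowSums(a)
    sf <- .scale_free_fit(k, n_bins)
    data.frame(power = beta, r_squared = sf$r2, slope = sf$slope,
               mean_k = mean(k))
  })
  fit_table <- do.call(rbind, fit)
  hit <- which(fit_table$r_squared >= r2_target)
  power <- if (length(hit) > 0) fit_table$power[hit[1]] else
    fit_table$power[which.max(fit_table$r_squared)]
  list(power = power, fit_table = fit_table)
}

# scale-free topology fit: binned log-log regression of p(k) on k
.scale_free_fit <- function(k, n_bins = 10L) {
  if (stats::sd(k) == 0) return(list(r2 = 0, slope = 0))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(km) & km > 0
  if (sum(ok) < 3) return(list(r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = if (is.finite(slope) && slope < 0) r2 else 0, slope = slope)
}

#' Topological overlap dissimilarity
#'
#' Computes the topological overlap matrix of an adjacency `a`:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`, and returns `1 - TOM`
#' (zero diagonal). TOM counts shared network neighbours, so two analytes
#' are similar when they connect to the same parts of the network even if
#' their direct adjacency is modest.
#'
#' @param a symmetric adjacency matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @return Symmetric dissimilarity matrix in \[0, 1\] with zero diagonal.
#' @export
tom_dissimilarity <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a), tol = 1e-12)) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  d <- 1 - tom
  diag(d) <- 0
  # numerical guard: symmetric to machine tolerance, clipped to [0, 1]
  d <- (d + t(d)) / 2
  pmin(pmax(d, 0), 1)
}

#' Detect metabolite modules from a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity, with an
#' adaptive branch cut: candidate cut heights are scanned over the merge
#' heights of the tree, and the cut retained is the one producing the most
#' branches of at least `min_size` members (ties broken towards assigning
#' more metabolites to modules, then towards the higher cut). Branches
#' smaller than `min_size` are labelled `"unclustered"`. Module labels are
#' `module_1, module_2, ...` in decreasing size order, so the partition is
#' stable under input permutation up to relabelling. The tree cut seeds the
#' modules; [metabolite_modules()] additionally refines membership against
#' the eigenmetabolites (prune/adopt/merge), which is the recommended
#' entry point on raw data.
#'
#' @param d square dissimilarity matrix (e.g. from [tom_dissimilarity()]).
#' @param min_size minimum module size (default 10).
#' @param x optional samples x metabolite matrix; when supplied,
#'   eigenmetabolites and their explained variance are computed per module.
#' @param max_height_frac branches are only recognised below this fraction
#'   of the tree's top merge height (default 0.99): objects that join the
#'   tree only at its very top share no topological overlap and stay
#'   unclustered rather than forming a spurious catch-all module.
#' @param power,notes bookkeeping fields stored on the result.
#' @return An object of class `module_set`: list with `assignment` (named
#'   character, `"unclustered"` allowed), `eigenmetabolites` (samples x
#'   module matrix or `NULL`), `variance_explained`, `power`,
#'   `min_module_size`, `tree` (the `hclust` object) and `cut_height`.
#' @export
detect_modules <- function(d, min_size = 10L, x = NULL,
                           max_height_frac = 0.99, power = NA_integer_,
                           notes = NULL) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- colnames(d)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(nrow(d)))
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  # guard against tiny floating-point inversions in the merge heights
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  cap <- max_height_frac * max(tree$height)
  heights <- sort(unique(tree$height))
  cuts <- unique(c(heights[heights <= cap] - 1e-10, cap))
  best <- NULL
  for (h in cuts) {
    grp <- stats::cutree(tree, h = h)
    sizes <- table(grp)
    n_big <- sum(sizes >= min_size)
    n_in <- sum(sizes[sizes >= min_size])
    cand <- c(n_big, n_in, h)
    if (is.null(best) || cand[1] > best$score[1] ||
        (cand[1] == best$score[1] && cand[2] > best$score[2]) ||
        (cand[1] == best$score[1] && cand[2] == best$score[2] &&
         cand[3] > best$score[3])) {
      best <- list(score = cand, grp = grp, h = h)
    }
  }
  grp <- best$grp
  sizes <- table(grp)
  big <- names(sizes)[sizes >= min_size]
  big <- big[order(-sizes[big])]
  assignment <- rep("unclustered", length(ids))
  names(assignment) <- ids
  for (i in seq_along(big))
    assignment[grp == as.integer(big[i])] <- sprintf("module_%d", i)
  ms <- structure(list(assignment = assignment, eigenmetabolites = NULL,
                       variance_explained = NULL, power = power,
                       min_module_size = as.integer(min_size), tree = tree,
                       cut_height = best$h, notes = notes),
                  class = "module_set")
  if (!is.null(x)) ms <- .fill_eigenmetabolites(ms, .table_matrix(x))
  ms
}

# Eigenmetabolite-based membership refinement, run to a fixed point:
# (i) merge module pairs whose eigenmetabolites correlate above `merge_cor`
# (fragments of one co-occurrence structure split by an aggressive soft
# power); (ii) prune members whose module-membership correlation |kME| falls
# below `kme_min` (loosely attached noise absorbed by the branch cut);
# (iii) adopt unclustered metabolites with |kME| >= `kme_min` to some
# module. The final membership rule is therefore uniform: a metabolite
# belongs to a module iff its correlation with that module's eigenmetabolite
# reaches `kme_min`. Modules below `min_size` dissolve.
.refine_modules <- function(x, assignment, min_size, kme_min = 0.5,
                            merge_cor = 0.75, max_iter = 20L) {
  lab <- assignment
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    mods <- setdiff(unique(lab), "unclustered")
    # merge the closest eigen-correlated pair
    if (length(mods) >= 2) {
      eig <- vapply(mods, function(g)
        eigenmetabolite(x[, names(lab)[lab == g], drop = FALSE])$profile,
        numeric(nrow(x)))
      ec <- abs(stats::cor(eig))
      diag(ec) <- 0
      if (max(ec) > merge_cor) {
        mx <- which(ec == max(ec), arr.ind = TRUE)[1, ]
        lab[lab == mods[mx[2]]] <- mods[mx[1]]
        changed <- TRUE
      }
    }
    # prune weak members, adopt strong outsiders
    mods <- setdiff(unique(lab), "unclustered")
    if (length(mods) > 0) {
      eig <- vapply(mods, function(g)
        eigenmetabolite(x[, names(lab)[lab == g], drop = FALSE])$profile,
        numeric(nrow(x)))
      kme <- abs(stats::cor(x[, names(lab), drop = FALSE], eig))
      best <- apply(kme, 1, which.max)
      strength <- kme[cbind(seq_along(best), best)]
      new_lab <- ifelse(strength >= kme_min, mods[best], "unclustered")
      names(new_lab) <- names(lab)
      if (!identical(unname(new_lab), unname(lab))) changed <- TRUE
      lab <- new_lab
    }
    for (g in setdiff(unique(lab), "unclustered"))
      if (sum(lab == g) < min_size) lab[lab == g] <- "unclustered"
    if (!changed) break
  }
  # relabel in decreasing size order for stability
  mods <- setdiff(unique(lab), "unclustered")
  if (length(mods) > 0) {
    sizes <- vapply(mods, function(g) sum(lab == g), integer(1))
    mods <- mods[order(-sizes, mods)]
    out <- lab
    for (i in seq_along(mods)) out[lab == mods[i]] <- sprintf("module_%d", i)
    lab <- out
  }
  lab
}

.fill_eigenmetabolites <- function(ms, x) {
  mods <- setdiff(sort(unique(ms$assignment)), "unclustered")
  if (length(mods) == 0) return(ms)
  eig <- matrix(NA_real_, nrow(x), length(mods),
                dimnames = list(rownames(x), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- names(ms$assignment)[ms$assignment == m]
    e <- eigenmetabolite(x[, members, drop = FALSE])
    eig[, m] <- e$profile
    ve[m] <- e$variance_explained
  }
  ms$eigenmetabolites <- eig
  ms$variance_explained <- ve
  ms
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$assignment), "unclustered"))
  cat(sprintf("module_set: %d modules, %d clustered / %d unclustered metabolites\n",
              n_mod, sum(x$assignment != "unclustered"),
              sum(x$assignment == "unclustered")))
  invisible(x)
}

#' Eigenmetabolite of a metabolite module
#'
#' The module summary profile: each member metabolite is standardised
#' (z-scored) across samples and the first left singular vector of the
#' resulting samples x members matrix is taken as the eigenmetabolite,
#' sign-oriented so that its mean correlation with the members is positive.
#' The explained variance is the first squared singular value over the total.
#'
#' @param x samples x members matrix for one module (>= 2 members).
#' @return list with `profile` (unit-norm per-sample numeric vector) and
#'   `variance_explained` in (0, 1\].
#' @export
eigenmetabolite <- function(x) {
  x <- .table_matrix(x)
  if (ncol(x) < 2) stop("module must have at least 2 members")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all-constant module: eigenmetabolite undefined")
  if (any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  z <- scale(x)
  sv <- svd(z)
  profile <- sv$u[, 1]
  if (mean(stats::cor(profile, z)) < 0) profile <- -profile
  names(profile) <- rownames(x)
  list(profile = profile,
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Validate a module partition against independent clusterings
#'
#' Reports the mean silhouette width of the clustered metabolites on
#' `1 - Pearson` distances, the cophenetic correlation between the module
#' tree and the input dissimilarity, and the adjusted Rand agreement of the
#' module partition with (i) plain average-linkage clustering of
#' `1 - Pearson` distances and (ii) k-means on the metabolite profiles, both
#' at k = number of modules.
#'
#' @param ms a `module_set` (needs >= 2 modules for silhouette/agreements).
#' @param x samples x metabolite matrix the modules were built from.
#' @param d optional dissimilarity used for the cophenetic comparison
#'   (defaults to `1 - Pearson`).
#' @return list with `mean_silhouette`, `cophenetic_corr`,
#'   `kmeans_agreement`, `plain_hclust_agreement` (silhouette and agreements
#'   are `NA` with a single module).
#' @export
validate_modules <- function(ms, x, d = NULL) {
  x <- .table_matrix(x)
  assignment <- ms$assignment[colnames(x)]
  clustered <- names(assignment)[assignment != "unclustered"]
  mods <- setdiff(unique(assignment), "unclustered")
  k <- length(mods)
  pearson_d <- 1 - stats::cor(x)
  coph <- if (!is.null(ms$tree)) {
    dd <- if (is.null(d)) pearson_d else as.matrix(d)
    stats::cor(stats::as.dist(dd[ms$tree$labels, ms$tree$labels]),
               stats::cophenetic(ms$tree))
  } else NA_real_
  if (k < 2) {
    return(list(mean_silhouette = NA_real_, cophenetic_corr = coph,
                kmeans_agreement = NA_real_, plain_hclust_agreement = NA_real_))
  }
  lab <- as.integer(factor(assignment[clustered]))
  sil <- cluster::silhouette(lab,
                             stats::as.dist(pearson_d[clustered, clustered]))
  mean_sil <- mean(sil[, "sil_width"])
  # comparison 1: average-linkage on 1 - Pearson directly
  plain <- stats::cutree(stats::hclust(
    stats::as.dist(pearson_d[clustered, clustered]), method = "average"), k = k)
  # comparison 2: k-means on the metabolite profiles
  km <- stats::kmeans(t(scale(x[, clustered, drop = FALSE])), centers = k,
                      nstart = 10)$cluster
  list(mean_silhouette = mean_sil,
       cophenetic_corr = coph,
       kmeans_agreement = mclust::adjustedRandIndex(lab, km),
       plain_hclust_agreement = mclust::adjustedRandIndex(lab, plain))
}

#' Combine module eigenmetabolites with unclustered metabolites
#'
#' The analyte matrix used for downstream inter-omic analysis: one column
#' per module (its eigenmetabolite profile) concatenated with the raw
#' columns of the unclustered metabolites.
#'
#' @param ms a `module_set` with eigenmetabolites computed.
#' @param x samples x metabolite matrix.
#' @return samples x analyte numeric matrix.
#' @export
combine_with_unclustered <- function(ms, x) {
  x <- .table_matrix(x)
  uncl <- names(ms$assignment)[ms$assignment == "unclustered"]
  uncl <- intersect(colnames(x), uncl)
  eig <- ms$eigenmetabolites
  if (is.null(eig)) return(x[, uncl, drop = FALSE])
  cbind(eig[rownames(x), , drop = FALSE], x[, uncl, drop = FALSE])
}

#' Build metabolite modules end to end
#'
#' The recommended construction: picks (or accepts) the soft power, forms
#' the unsigned adjacency and TOM dissimilarity, seeds modules with the
#' adaptive branch cut, and refines membership against the module
#' eigenmetabolites -- merging modules whose eigenmetabolites correlate
#' above `merge_cor`, pruning members with module-membership correlation
#' |kME| below `kme_min` and adopting unclustered metabolites above it,
#' iterated to a fixed point. The refinement makes the final partition
#' robust to the soft-power choice: a low power lets the branch cut absorb
#' loosely correlated noise (pruned away), a high power fragments modules
#' (merged and re-adopted). The default `kme_min = 0.5` corresponds to
#' roughly three null standard deviations of a correlation at ~50 samples.
#'
#' @param x samples x metabolite matrix or [metabolite_table()].
#' @param power `"auto"` (choose by scale-free fit) or a fixed integer.
#' @param min_size minimum module size.
#' @param kme_min membership threshold on the |correlation| with the module
#'   eigenmetabolite.
#' @param merge_cor eigenmetabolite correlation above which two modules are
#'   considered fragments of one structure and merged.
#' @return A `module_set`.
#' @export
metabolite_modules <- function(x, power = "auto", min_size = 10L,
                               kme_min = 0.5, merge_cor = 0.75) {
  m <- .table_matrix(x)
  if (identical(power, "auto")) {
    # The scale-free criterion is designed for scale-free networks; on
    # modular-plus-noise correlation structure its R^2 sequence is
    # non-monotone and can land on extreme powers. Constrain the automatic
    # choice to the conventional unsigned-network range: the field's
    # sample-size fallback (6) up to the largest power at which a strong
    # within-module correlation of ~0.8 still keeps a few percent
    # adjacency (14). Explicit `power` bypasses the constraint.
    power <- min(max(pick_soft_threshold(m)$power, 6L), 14L)
  }
  a <- abs(stats::cor(m))^power
  diag(a) <- 0
  d <- tom_dissimilarity(a)
  dimnames(d) <- list(colnames(m), colnames(m))
  ms <- detect_modules(d, min_size = min_size, power = as.integer(power))
  ms$assignment <- .refine_modules(m, ms$assignment, min_size,
                                   kme_min = kme_min, merge_cor = merge_cor)
  .fill_eigenmetabolites(ms, m)
}

#' Write a module assignment table
#'
#' Tab-delimited `(feature_id, mode, mz, rt, module_label)`.
#'
#' @param ms a `module_set`.
#' @param mets the [metabolite_table()] carrying feature metadata.
#' @param path output path.
#' @export
write_module_assignment <- function(ms, mets, path) {
  meta <- mets$feature_meta
  df <- data.frame(feature_id = meta$feature_id, mode = meta$mode,
                   mz = meta$mz, rt = meta$rt,
                   module_label = unname(ms$assignment[meta$feature_id]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
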