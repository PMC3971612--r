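#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`.
#' Samples whose total count is below `depth` are dropped with a warning
#' (their ids are recorded in the `dropped_samples` attribute). Deterministic
#' given `seed`.
#'
#' @param t an [otu_table()].
#' @param depth target reads per sample (default 30000).
#' @param seed integer seed.
#' @return A rarefied [otu_table()]; every retained sample sums to `depth`.
#' @export
rarefy <- function(t, depth = 30000L, seed = 1L) {
  stopifnot(inherits(t, "otu_table"))
  if (depth <= 0) stop("depth must be > 0")
  set.seed(seed)
  totals <- rowSums(t$counts)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(t$counts)[!keep], collapse = ", ")))
  }
  counts <- t$counts[keep, , drop = FALSE]
  out <- counts
  for (i in seq_len(nrow(counts))) {
    if (totals[keep][i] == depth) next  # already at depth: unchanged
    reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
    picked <- sample(reads, depth, replace = FALSE)
    out[i, ] <- tabulate(picked, nbins = ncol(counts))
  }
  res <- otu_table(out, t$taxonomy)
  attr(res, "dropped_samples") <- rownames(t$counts)[!keep]
  res
}

#' Keep features detected in a minimum number of samples
#'
#' Retains features (OTUs or metabolites) whose value exceeds `detection` in
#' at least `min_samples` samples ("at least" is inclusive: a feature present
#' in exactly `min_samples` samples is kept). Column order is preserved and
#' the filter is idempotent.
#'
#' @param t an [otu_table()], [metabolite_table()] or plain matrix
#'   (samples x features).
#' @param min_samples minimum number of samples with detection, >= 1.
#' @param detection detection threshold; a feature counts as present in a
#'   sample when its value is strictly greater than this.
#' @return A table of the same class with only the retained features.
#' @export
filter_min_samples <- function(t, min_samples, detection = 0) {
  stopifnot(min_samples >= 1)
  m <- .table_matrix(t)
  n_detect <- colSums(m > detection)
  .table_subset(t, colnames(m)[n_detect >= min_samples])
}

#' Remove rare analytes by above-background prevalence
#'
#' Removes analytes measured above background in strictly fewer than
#' `min_fraction` of subjects; the default fraction is 0.18, and the boundary
#' is inclusive (an analyte detected in exactly 18% of subjects is retained,
#' since 18% is not fewer than 18%). "Above background" is operationalised as
#' strictly greater than `background` (default 0); the study data's upstream
#' processing defines no explicit background level, so the threshold is
#' configurable.
#'
#' @param t an [otu_table()], [metabolite_table()] or matrix.
#' @param min_fraction minimum above-background prevalence in \[0, 1\].
#' @param background background intensity/count level.
#' @return A table of the same class with rare analytes removed.
#' @export
filter_prevalence <- function(t, min_fraction = 0.18, background = 0) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  m <- .table_matrix(t)
  prevalence <- colSums(m > background) / nrow(m)
  .table_subset(t, colnames(m)[prevalence >= min_fraction])
}
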