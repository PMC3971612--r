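# shared fixtures built in code

# tiny OTU table with known taxonomy
toy_otu <- function() {
  counts <- matrix(c(10, 0, 5,
                     3, 7, 0,
                     0, 2, 8,
                     4, 4, 4), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("S", 1:4), paste0("OTU", 1:3)))
  tax <- c(
    OTU1 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__Blautia;s__",
    OTU2 = "k__Bacteria;p__Firmicutes;c__;o__;f__;g__Blautia;s__",
    OTU3 = "k__Bacteria;p__Bacteroidetes;c__;o__;f__;g__Bacteroides;s__")
  otu_table(counts, tax)
}

# a small correlated-block metabolite matrix with known membership
block_metabolites <- function(n = 40, sizes = c(12, 13), rho = 0.9,
                              n_noise = 0, seed = 1) {
  set.seed(seed)
  cols <- list()
  truth <- character(0)
  for (b in seq_along(sizes)) {
    f <- rnorm(n)
    for (i in seq_len(sizes[b])) {
      cols[[length(cols) + 1]] <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)
      truth <- c(truth, sprintf("block_%d", b))
    }
  }
  for (i in seq_len(n_noise)) {
    cols[[length(cols) + 1]] <- rnorm(n)
    truth <- c(truth, "noise")
  }
  x <- do.call(cbind, cols)
  dimnames(x) <- list(sprintf("S%02d", seq_len(n)),
                      sprintf("m%03d", seq_along(truth)))
  list(x = x, truth = stats::setNames(truth, colnames(x)))
}

# random symmetric adjacency in [0,1] with zero diagonal
random_adjacency <- function(p, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(p * p), p)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# naive double-loop TOM dissimilarity oracle
naive_tom_dissimilarity <- function(a) {
  p <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    out[i, j] <- 1 - (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exhaustive one-sided (greater) hypergeometric tail for a 2x2 table,
# as an explicit sum of hypergeometric point masses
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  sum(probs[supp >= a])
}

# paired synthetic bundle written to disk for pipeline tests
toy_bundle_paths <- function(dir, seed = 23) {
  cfg <- synth_config(seed = seed, n_subjects = 40, n_otus = 60,
                      n_metabolites = 60, n_modules = 2,
                      module_size_range = c(10, 12), n_planted_links = 15,
                      link_effect = 0.8, n_guilds = 2, guild_size = 8,
                      guild_corr = 0.7, read_depth_mean = 2000,
                      n_pathways = 12, shared_metabolite_fraction = 0.6)
  ds <- generate_paired_dataset(cfg)
  d1 <- file.path(dir, "r1"); d2 <- file.path(dir, "r2")
  p1 <- write_dataset_bundle(ds$region1, d1)
  p2 <- write_dataset_bundle(ds$region2, d2)
  list(region1 = as.list(p1), region2 = as.list(p2), truth = ds$truth)
}
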