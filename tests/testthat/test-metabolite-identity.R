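# monoisotopic mass oracle computed from atomic masses
atom <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
          S = 31.97207069)
mono_mass <- function(formula) {
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  sum(vapply(parts, function(p) {
    sym <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    atom[[sym]] * if (n == "") 1 else as.integer(n)
  }, numeric(1)))
}

test_that("glucose is identified at ~0 ppm through the protonated adduct", {
  db <- read_compound_db()
  glucose <- mono_mass("C6H12O6")  # oracle from atomic masses
  expect_equal(db$monoisotopic_mass[db$name == "D-Glucose"], glucose,
               tolerance = 1e-6)
  hits <- putative_ids(glucose + 1.007276, "ESI+", db)
  expect_equal(hits$name[1], "D-Glucose")
  expect_equal(hits$adduct[1], "[M+H]+")
  expect_lt(abs(hits$ppm_error[1]), 0.1)
  # far-off query returns an empty list (a valid result)
  none <- putative_ids(glucose + 11, "ESI+", db)
  expect_equal(nrow(none), 0L)
  # negative mode matches through deprotonation
  hneg <- putative_ids(glucose - 1.007276, "ESI-", db)
  expect_equal(hneg$name[1], "D-Glucose")
  expect_equal(hneg$adduct[1], "[M-H]-")
})

test_that("ppm window is inclusive and monotone", {
  db <- read_compound_db()
  m <- db$monoisotopic_mass[db$name == "L-Tryptophan"]
  # just inside the 20 ppm window: retained; just outside: dropped
  at20 <- putative_ids((m * (1 + 19.99e-6)) + 1.007276, "ESI+", db, ppm = 20)
  expect_true("L-Tryptophan" %in% at20$name)
  just_out <- putative_ids((m * (1 + 20.5e-6)) + 1.007276, "ESI+", db, ppm = 20)
  expect_false("L-Tryptophan" %in% just_out$name)
  # candidates at ppm 10 are a subset of candidates at ppm 20
  for (mz in c(181.07, 205.10, 126.02)) {
    narrow <- putative_ids(mz, "ESI+", db, ppm = 10)$compound_id
    wide <- putative_ids(mz, "ESI+", db, ppm = 20)$compound_id
    expect_true(all(narrow %in% wide))
  }
})

test_that("origin-class filtering is a post-filter on candidates", {
  db <- read_compound_db()
  m <- db$monoisotopic_mass[db$name == "Butyric acid"]
  all_hits <- putative_ids(m + 1.007276, "ESI+", db)
  bact <- putative_ids(m + 1.007276, "ESI+", db, origin_filter = "bacterial")
  expect_true(all(bact$origin_class == "bacterial"))
  expect_true(all(bact$compound_id %in% all_hits$compound_id))
})

test_that("cross-region matching enforces both tolerances jointly", {
  a <- data.frame(feature_id = c("a1", "a2", "a3"),
                  mz = c(100.000, 200.000, 300.000),
                  rt = c(1.00, 2.00, 3.00), mode = "ESI+")
  b <- data.frame(feature_id = c("b1", "b2", "b3"),
                  mz = c(100.000, 200.004, 300.004),
                  rt = c(1.00, 2.05, 3.01), mode = "ESI+")
  m <- match_across_regions(a, b)
  # identical feature matches; dmz ok but drt = 0.05 fails the joint rule
  expect_true(any(m$pairs$feature_a == "a1" & m$pairs$feature_b == "b1"))
  expect_false("a2" %in% m$pairs$feature_a)
  expect_true(any(m$pairs$feature_a == "a3" & m$pairs$feature_b == "b3"))
  expect_setequal(m$unmatched_a, "a2")
  # different ion modes never match
  b_mode <- transform(b, mode = "ESI-")
  expect_equal(nrow(match_across_regions(a, b_mode)$pairs), 0L)
})

test_that("matching is greedy one-to-one and symmetric", {
  a <- data.frame(feature_id = c("a1", "a2"),
                  mz = c(150.0000, 150.0030), rt = c(5.00, 5.00), mode = "ESI+")
  b <- data.frame(feature_id = "b1", mz = 150.0001, rt = 5.01, mode = "ESI+")
  m <- match_across_regions(a, b)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$feature_a, "a1")  # closer mass wins the tie
  ab <- match_across_regions(a, b)$pairs
  ba <- match_across_regions(b, a)$pairs
  expect_setequal(paste(ab$feature_a, ab$feature_b),
                  paste(ba$feature_b, ba$feature_a))
})

test_that("synthetic paired regions are matched at the jitter-model recall", {
  cfg <- synth_config(seed = 19, n_subjects = 20, n_otus = 40,
                      n_metabolites = 120, n_modules = 2,
                      module_size_range = c(10, 12), n_planted_links = 5,
                      read_depth_mean = 2000, n_pathways = 10,
                      shared_metabolite_fraction = 0.5,
                      mass_jitter_sd = 0.001, rt_jitter_sd = 0.01)
  ds <- generate_paired_dataset(cfg)
  m <- match_across_regions(ds$region1$metabolites, ds$region2$metabolites)
  truth <- ds$truth$shared_metabolite_pairs
  hit <- paste(m$pairs$feature_a, m$pairs$feature_b)
  recall <- mean(paste(truth$feature_region1, truth$feature_region2) %in% hit)
  # oracle: P(|N(0,.001)| <= .005) * P(|N(0,.01)| <= .04), modes always equal
  p_mass <- 1 - 2 * pnorm(-0.005 / 0.001)
  p_rt <- 1 - 2 * pnorm(-0.04 / 0.01)
  expected <- p_mass * p_rt  # ~0.9999
  expect_gte(recall, expected - 3 * sqrt(expected * (1 - expected) / nrow(truth)) - 0.02)
})
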