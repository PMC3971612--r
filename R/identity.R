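#' Adduct rules for electrospray ionisation
#'
#' The fixed adduct table used for putative identification: protonation and
#' sodiation in positive mode (`[M+H]+`, `[M+Na]+`), deprotonation and
#' chloride attachment in negative mode (`[M-H]-`, `[M+Cl]-`). Mass shifts
#' are in daltons; the proton and sodium shifts carry the electron-mass
#' correction, the chloride shift uses the atomic mass (a documented
#' constant choice).
#'
#' @return data.frame with columns `mode`, `name`, `mass_shift`,
#'   `charge_sign`.
#' @export
adduct_rules <- function() {
  data.frame(
    mode = c("ESI+", "ESI+", "ESI-", "ESI-"),
    name = c("[M+H]+", "[M+Na]+", "[M-H]-", "[M+Cl]-"),
    mass_shift = c(1.007276, 22.989218, -1.007276, 34.968853),
    charge_sign = c(1L, 1L, -1L, -1L),
    stringsAsFactors = FALSE)
}

#' Load a compound mass table
#'
#' Reads a tab-delimited compound database with columns `compound_id`,
#' `name`, `monoisotopic_mass`, `source_db`, `kegg_pathways`
#' (comma-separated labels, may be empty) and `origin_class`
#' (`mammalian`/`bacterial`/`plant`/`unknown`). A small curated table of
#' common gut metabolites ships with the package as
#' `system.file("extdata", "compounds.tsv", package = "syntropy")`.
#'
#' @param path file path; defaults to the packaged table.
#' @return data.frame of class `compound_db`.
#' @export
read_compound_db <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compounds.tsv", package = "syntropy")
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "name", "monoisotopic_mass", "source_db",
            "kegg_pathways", "origin_class")
  if (!all(need %in% names(db)))
    stop("compound db must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(db$compound_id)) stop("duplicate compound_id in db")
  if (any(db$monoisotopic_mass <= 0)) stop("monoisotopic masses must be positive")
  structure(db, class = c("compound_db", "data.frame"))
}

#' Putative compound identification by adduct-adjusted exact mass
#'
#' For each adduct rule of the feature's ionisation mode, the neutral mass
#' is `mz - mass_shift`; database compounds whose monoisotopic mass lies
#' within `ppm` parts per million of the neutral mass are candidate
#' identifications (`|neutral - monoisotopic| / monoisotopic * 1e6 <= ppm`,
#' boundary inclusive). An empty candidate list is a valid result.
#'
#' @param mz observed m/z, expected within the instrument range.
#' @param mode `"ESI+"` or `"ESI-"`.
#' @param db a `compound_db` (default: the packaged table).
#' @param ppm mass window in parts per million (default 20).
#' @param origin_filter optional subset of origin classes to retain (e.g.
#'   `c("bacterial", "mammalian")`).
#' @param instrument_range acquisition range check for `mz` (default
#'   50-850).
#' @return data.frame of candidates sorted by `|ppm_error|`: `compound_id`,
#'   `name`, `adduct`, `neutral_mass`, `ppm_error`, `kegg_pathways`,
#'   `origin_class`.
#' @export
putative_ids <- function(mz, mode = c("ESI+", "ESI-"), db = NULL, ppm = 20,
                         origin_filter = NULL,
                         instrument_range = c(50, 850)) {
  mode <- match.arg(mode)
  if (mz < instrument_range[1] || mz > instrument_range[2])
    stop(sprintf("m/z %.4f outside instrument range [%g, %g]",
                 mz, instrument_range[1], instrument_range[2]))
  if (is.null(db)) db <- read_compound_db()
  rules <- adduct_rules()
  rules <- rules[rules$mode == mode, , drop = FALSE]
  hits <- lapply(seq_len(nrow(rules)), function(i) {
    neutral <- mz - rules$mass_shift[i]
    err <- (neutral - db$monoisotopic_mass) / db$monoisotopic_mass * 1e6
    ok <- abs(err) <= ppm
    if (!any(ok)) return(NULL)
    data.frame(compound_id = db$compound_id[ok], name = db$name[ok],
               adduct = rules$name[i], neutral_mass = neutral,
               ppm_error = err[ok], kegg_pathways = db$kegg_pathways[ok],
               origin_class = db$origin_class[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(compound_id = character(0), name = character(0),
                      adduct = character(0), neutral_mass = numeric(0),
                      ppm_error = numeric(0), kegg_pathways = character(0),
                      origin_class = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(origin_filter))
    out <- out[out$origin_class %in% origin_filter, , drop = FALSE]
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match metabolite features across two regions
#'
#' Identifies the same metabolite measured in two datasets: a pair of
#' features matches only when BOTH the mass difference is at most
#' `max_dmass` m/z AND the retention-time difference is at most `max_drt`
#' minutes (both boundaries inclusive), within the same ionisation mode.
#' Among all qualifying pairs, matching is greedy one-to-one by ascending
#' combined normalised distance (`|dmz|/max_dmass + |drt|/max_drt`), ties
#' broken by the smaller mass difference. The result is symmetric in its
#' arguments.
#'
#' @param a,b [metabolite_table()] objects (or their `feature_meta`
#'   data.frames).
#' @param max_dmass mass tolerance in m/z (default 0.005).
#' @param max_drt retention-time tolerance in minutes (default 0.04).
#' @return list with `pairs` (data.frame `feature_a`, `feature_b`, `dmz`,
#'   `drt`), `unmatched_a`, `unmatched_b`.
#' @export
match_across_regions <- function(a, b, max_dmass = 0.005, max_drt = 0.04) {
  ma <- if (inherits(a, "metabolite_table")) a$feature_meta else a
  mb <- if (inherits(b, "metabolite_table")) b$feature_meta else b
  cand <- NULL
  for (md in intersect(unique(ma$mode), unique(mb$mode))) {
    ia <- which(ma$mode == md)
    ib <- which(mb$mode == md)
    if (length(ia) == 0 || length(ib) == 0) next
    dmz <- abs(outer(ma$mz[ia], mb$mz[ib], "-"))
    drt <- abs(outer(ma$rt[ia], mb$rt[ib], "-"))
    # inclusive boundaries, guarded against floating-point representation
    # error in the differences (1.04 - 1.00 > 0.04 in binary arithmetic)
    eps <- 1e-9
    ok <- which(dmz <= max_dmass + eps & drt <= max_drt + eps, arr.ind = TRUE)
    if (nrow(ok) == 0) next
    cand <- rbind(cand, data.frame(
      feature_a = ma$feature_id[ia[ok[, 1]]],
      feature_b = mb$feature_id[ib[ok[, 2]]],
      dmz = dmz[ok], drt = drt[ok], stringsAsFactors = FALSE))
  }
  pairs <- data.frame(feature_a = character(0), feature_b = character(0),
                      dmz = numeric(0), drt = numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(cand) && nrow(cand) > 0) {
    score <- cand$dmz / max_dmass + cand$drt / max_drt
    cand <- cand[order(score, cand$dmz, cand$feature_a, cand$feature_b), ,
                 drop = FALSE]
    used_a <- used_b <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$feature_a[i] %in% used_a || cand$feature_b[i] %in% used_b) next
      keep[i] <- TRUE
      used_a <- c(used_a, cand$feature_a[i])
      used_b <- c(used_b, cand$feature_b[i])
    }
    pairs <- cand[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       unmatched_a = setdiff(ma$feature_id, pairs$feature_a),
       unmatched_b = setdiff(mb$feature_id, pairs$feature_b))
}
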