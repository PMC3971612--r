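#' Construct an OTU count table
#'
#' The basic microbiome observation: a sample x OTU matrix of non-negative
#' integer read counts plus a GreenGenes-style 7-rank taxonomy string per OTU
#' (`kingdom;phylum;class;order;family;genus;species`, ranks may be empty).
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Row and
#'   column names are taken as sample and OTU identifiers.
#' @param taxonomy named character vector mapping every OTU id to its
#'   taxonomy string.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (named character).
#' @export
otu_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  # a 0-OTU table is valid; R normalises zero-length dimnames to NULL
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in OTU table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in OTU table")
  if (any(counts < 0)) stop("negative counts in OTU table")
  taxonomy <- taxonomy[colnames(counts)]
  if (anyNA(taxonomy))
    stop("every OTU id must have a taxonomy entry; missing: ",
         paste(setdiff(colnames(counts), names(taxonomy)), collapse = ", "))
  if (ncol(counts) > 0) names(taxonomy) <- colnames(counts)
  storage.mode(counts) <- "double"
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (total reads %.0f)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Construct a metabolite feature table
#'
#' Sample x feature intensity matrix from UPLC-MS, with per-feature mass
#' spectrometry metadata: m/z, retention time (minutes) and ionisation mode.
#'
#' @param intensities numeric matrix, samples in rows, features in columns;
#'   all values must be non-negative.
#' @param feature_meta data.frame with columns `feature_id`, `mz`, `rt`,
#'   `mode` (one of `"ESI+"`, `"ESI-"`); one row per feature column.
#' @return An object of class `metabolite_table`.
#' @export
metabolite_table <- function(intensities, feature_meta) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensities must have sample row names and feature column names")
  if (any(intensities < 0)) stop("negative intensities")
  stopifnot(all(c("feature_id", "mz", "rt", "mode") %in% names(feature_meta)))
  feature_meta <- feature_meta[match(colnames(intensities), feature_meta$feature_id), ,
                               drop = FALSE]
  if (anyNA(feature_meta$feature_id))
    stop("feature_meta must cover every intensity column")
  if (any(feature_meta$mz <= 0)) stop("m/z values must be positive")
  if (any(feature_meta$rt < 0)) stop("retention times must be non-negative")
  if (!all(feature_meta$mode %in% c("ESI+", "ESI-")))
    stop("mode must be 'ESI+' or 'ESI-'")
  rownames(feature_meta) <- NULL
  structure(list(intensities = intensities, feature_meta = feature_meta),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d samples x %d features (%d ESI+, %d ESI-)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$feature_meta$mode == "ESI+"),
              sum(x$feature_meta$mode == "ESI-")))
  invisible(x)
}

#' Construct a per-OTU pathway abundance profile
#'
#' OTU x pathway matrix of relative genomic pathway proportions, i.e. the
#' consumption-side shape of imputed-metagenome output (per-OTU metagenomes
#' sorted into KEGG pathways). Rows may be renormalised to sum to one.
#'
#' @param abundance numeric matrix, OTUs in rows, pathways in columns,
#'   non-negative.
#' @param normalize logical; renormalise each row to sum to 1 (rows that sum
#'   to zero are left as zeros).
#' @return An object of class `pathway_profile`.
#' @export
pathway_profile <- function(abundance, normalize = FALSE) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance must have OTU row names and pathway column names")
  if (any(abundance < 0)) stop("pathway abundances must be non-negative")
  if (normalize) {
    rs <- rowSums(abundance)
    abundance[rs > 0, ] <- abundance[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  structure(list(abundance = abundance), class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("pathway_profile: %d OTUs x %d pathways\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

# shared accessor: the numeric sample x feature matrix of a table
.table_matrix <- function(t) {
  if (inherits(t, "otu_table")) return(t$counts)
  if (inherits(t, "metabolite_table")) return(t$intensities)
  if (is.matrix(t)) return(t)
  stop("expected an otu_table, metabolite_table or matrix")
}

# rebuild a table of the same class with a feature subset
.table_subset <- function(t, keep_features) {
  if (inherits(t, "otu_table")) {
    otu_table(t$counts[, keep_features, drop = FALSE],
              t$taxonomy[keep_features])
  } else if (inherits(t, "metabolite_table")) {
    metabolite_table(t$intensities[, keep_features, drop = FALSE],
                     t$feature_meta[t$feature_meta$feature_id %in% keep_features, ,
                                    drop = FALSE])
  } else {
    t[, keep_features, drop = FALSE]
  }
}

# parse 7-rank taxonomy strings into a matrix of ranks
.split_taxonomy <- function(tax) {
  parts <- strsplit(tax, ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- 7L
    p
  }, character(7)))
  colnames(out) <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")
  rownames(out) <- names(tax)
  out
}

# rank extraction with GreenGenes prefixes stripped; "" / "g__" -> NA
.tax_rank <- function(tax, rank) {
  m <- .split_taxonomy(tax)[, rank]
  m <- sub("^[a-z]__", "", m)
  m[is.na(m) | m == ""] <- NA_character_
  m
}
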