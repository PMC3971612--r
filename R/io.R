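#' Read and write classic tab-delimited OTU tables
#'
#' The classic dialect has one row per OTU, one column per sample and a final
#' `taxonomy` column; `orientation = "samples_as_rows"` accepts the transpose
#' (samples in rows, taxonomy supplied in the header-named last row is not
#' meaningful there, so the transpose dialect carries taxonomy in a final
#' `taxonomy` *row* is not supported -- the transposed dialect instead expects
#' the last *column* to be absent and taxonomy to be attached separately).
#' Writers emit UTF-8 with LF line endings.
#'
#' @param path file path.
#' @param orientation `"otus_as_rows"` (classic, default) or
#'   `"samples_as_rows"`.
#' @return [read_otu_table()] returns an [otu_table()];
#'   [write_otu_table()] invisibly returns `path`.
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: ", path)
  # sentinel suffix so strsplit keeps trailing empty fields (empty taxonomy)
  cells <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  cells <- lapply(cells, function(x) {
    x[length(x)] <- sub("\x01$", "", x[length(x)])
    x
  })
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad, widths[1], widths[bad]))
  }
  header <- cells[[1]]
  body <- cells[-1]
  if (orientation == "otus_as_rows") {
    if (header[length(header)] != "taxonomy")
      stop("parse error at line 1: last column must be named 'taxonomy'")
    sample_ids <- header[-c(1, length(header))]
    if (length(body) == 0) {
      counts <- matrix(0, nrow = length(sample_ids), ncol = 0,
                       dimnames = list(sample_ids, character(0)))
      return(otu_table(counts, stats::setNames(character(0), character(0))))
    }
    otu_ids <- vapply(body, `[[`, character(1), 1)
    taxonomy <- vapply(body, function(x) x[[length(x)]], character(1))
    counts <- matrix(0, length(otu_ids), length(sample_ids),
                     dimnames = list(otu_ids, sample_ids))
    for (i in seq_along(body)) {
      vals <- suppressWarnings(as.numeric(body[[i]][-c(1, length(body[[i]]))]))
      if (anyNA(vals)) {
        j <- which(is.na(vals))[1]
        stop(sprintf("parse error at line %d: non-numeric count in column '%s'",
                     i + 1L, sample_ids[j]))
      }
      if (any(vals < 0)) {
        j <- which(vals < 0)[1]
        stop(sprintf(
          "parse error at line %d: negative count %s for OTU '%s', sample '%s'",
          i + 1L, format(vals[j]), otu_ids[i], sample_ids[j]))
      }
      counts[i, ] <- vals
    }
    if (anyDuplicated(otu_ids))
      stop(sprintf("parse error at line %d: duplicate OTU id '%s'",
                   which(duplicated(otu_ids))[1] + 1L,
                   otu_ids[duplicated(otu_ids)][1]))
    names(taxonomy) <- otu_ids
    otu_table(t(counts), taxonomy)
  } else {
    sample_ids <- vapply(body, `[[`, character(1), 1)
    otu_ids <- header[-1]
    counts <- matrix(0, length(sample_ids), length(otu_ids),
                     dimnames = list(sample_ids, otu_ids))
    for (i in seq_along(body)) {
      vals <- suppressWarnings(as.numeric(body[[i]][-1]))
      if (anyNA(vals) || any(vals < 0))
        stop(sprintf("parse error at line %d: invalid count", i + 1L))
      counts[i, ] <- vals
    }
    otu_table(counts, stats::setNames(rep("", length(otu_ids)), otu_ids))
  }
}

#' @rdname read_otu_table
#' @param x an [otu_table()].
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  con <- file(path, open = "wb")  # binary: force LF endings everywhere
  on.exit(close(con))
  header <- paste(c("otu_id", rownames(x$counts), "taxonomy"), collapse = "\t")
  rows <- vapply(seq_len(ncol(x$counts)), function(j) {
    paste(c(colnames(x$counts)[j], format(x$counts[, j], trim = TRUE,
                                          scientific = FALSE),
            x$taxonomy[j]), collapse = "\t")
  }, character(1))
  writeLines(enc2utf8(c(header, rows)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read and write metabolite feature tables
#'
#' Tab-delimited with columns `feature_id`, `mz`, `rt`, `mode`, then one
#' column per sample; one row per feature.
#'
#' @param path file path.
#' @return [read_metabolite_table()] returns a [metabolite_table()].
#' @export
read_metabolite_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt", "mode")
  if (!all(need %in% names(df)))
    stop("metabolite table must have columns feature_id, mz, rt, mode")
  sample_cols <- setdiff(names(df), need)
  intens <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  colnames(intens) <- df$feature_id
  metabolite_table(intens, df[, need])
}

#' @rdname read_metabolite_table
#' @param x a [metabolite_table()].
#' @export
write_metabolite_table <- function(x, path) {
  stopifnot(inherits(x, "metabolite_table"))
  df <- cbind(x$feature_meta,
              as.data.frame(t(x$intensities), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write per-OTU pathway profiles
#'
#' Tab-delimited, one row per OTU (`otu_id` first column) and one column per
#' pathway.
#'
#' @param path file path.
#' @return [read_pathway_profile()] returns a [pathway_profile()].
#' @export
read_pathway_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "otu_id") stop("first column must be otu_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$otu_id
  pathway_profile(m)
}

#' @rdname read_pathway_profile
#' @param x a [pathway_profile()].
#' @export
write_pathway_profile <- function(x, path) {
  stopifnot(inherits(x, "pathway_profile"))
  df <- data.frame(otu_id = rownames(x$abundance),
                   as.data.frame(x$abundance, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
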