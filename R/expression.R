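# Expression handling: TSV count matrices, median-of-ratios size factors,
# FPM/FPKM normalization, log2(x+1), 5'-isomiR aggregation, isomiR
# selection by median-coverage, and the transcript low-expression filter.

#' Read / write a features-by-samples count matrix
#'
#' TSV layout: first column feature ids (header `feature_id` on write, any
#' name on read), remaining columns one per sample. Values may be
#' fractional (RSEM expected counts) but must be non-negative.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .stop_invalid("count matrix needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) .stop_invalid("duplicated feature ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m) || any(m < 0)) .stop_invalid("counts must be non-negative and complete")
  m
}

#' @param x matrix to write.
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' TSV with columns `sample_id`, `group`; every analyzed sample has exactly
#' one label.
#'
#' @param path file path.
#' @return data frame `sample_id`, `group`.
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    .stop_invalid("sample group table must have columns sample_id, group")
  }
  if (anyDuplicated(df$sample_id)) .stop_invalid("duplicated sample ids in group map")
  df[c("sample_id", "group")]
}

#' Median-of-ratios size factors
#'
#' For each feature with strictly positive counts in every sample, compute
#' its geometric mean across samples; each sample's size factor is the
#' median over those features of count / geometric mean. Fails loudly when
#' no feature is positive in all samples (no pseudo-reference fallback is
#' applied).
#'
#' @param counts non-negative features-by-samples matrix.
#' @return positive numeric vector of per-sample factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  if (any(counts < 0)) .stop_invalid("negative counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    .stop_invalid(
      "no feature has positive counts in every sample; ",
      "median-of-ratios size factors are undefined for this matrix"
    )
  }
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(log(counts[pos, , drop = FALSE]) - loggeo, 2, stats::median)
  sf <- exp(sf)
  if (any(!is.finite(sf) | sf <= 0)) .stop_invalid("non-positive size factor computed")
  sf
}

#' Normalize a count matrix to FPM or FPKM
#'
#' Counts are divided by per-sample size factors and rescaled to
#' per-million of the mean normalized library size (FPM); FPKM additionally
#' divides by feature length / 1000. Optionally applies the `log2(x + 1)`
#' transform.
#'
#' @param counts non-negative features-by-samples matrix.
#' @param size_factors per-sample factors; computed with
#'   [size_factors_median_of_ratios()] when `NULL`.
#' @param mode `"FPM"` or `"FPKM"`.
#' @param lengths per-feature lengths in nt (required for FPKM), named or
#'   in row order.
#' @param log2 apply `log2(x + 1)` to the normalized values.
#' @return matrix with attributes `normalization` (`"FPM"`/`"FPKM"`) and
#'   `log2` (logical).
#' @export
normalize_counts <- function(counts, size_factors = NULL,
                             mode = c("FPM", "FPKM"), lengths = NULL,
                             log2 = FALSE) {
  mode <- match.arg(mode)
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(counts)
  if (length(size_factors) != ncol(counts)) .stop_invalid("one size factor per sample")
  norm <- sweep(counts, 2, size_factors, "/")
  libs <- colSums(norm)
  out <- norm * (1e6 / mean(libs))
  if (mode == "FPKM") {
    if (is.null(lengths)) .stop_invalid("FPKM requires per-feature lengths")
    if (!is.null(names(lengths))) {
      lengths <- lengths[rownames(counts)]
    }
    if (length(lengths) != nrow(counts) || anyNA(lengths) || any(lengths <= 0)) {
      .stop_invalid("FPKM requires a positive length for every feature")
    }
    out <- out / (lengths / 1000)
  }
  if (log2) out <- log2(out + 1)
  attr(out, "normalization") <- mode
  attr(out, "log2") <- log2
  out
}

#' Aggregate 3'-variants into 5'-isomiR counts
#'
#' 3'-end variation does not alter the seed, so rows whose identifiers
#' share the same `"mirna_name|shift"` prefix are summed element-wise. Row
#' identifiers may be `"name|shift"` or `"name|shift|<3p-variant>"`; any
#' other form is an error naming the offending row. The total matrix sum is
#' preserved exactly.
#'
#' @param counts features-by-samples matrix with isomiR identifiers as
#'   rownames.
#' @return matrix keyed by 5'-isomiR id, rows in first-appearance order.
#' @export
aggregate_5prime_isomirs <- function(counts) {
  ids <- rownames(counts)
  if (is.null(ids)) .stop_invalid("counts must have isomiR identifiers as rownames")
  key <- parse_isomir_id(ids)$isomir
  out <- rowsum(counts, group = key, reorder = FALSE)
  # rowsum keeps first-appearance order with reorder = FALSE
  out
}

#' Select top isomiRs by median-expression coverage
#'
#' Sorts isomiRs by median expression (descending, ties broken
#' lexicographically by id) and returns the shortest prefix whose summed
#' medians reach `coverage` of the total median expression.
#'
#' @param medians named numeric vector of per-isomiR median expression.
#' @param coverage fraction of total median expression to cover, in (0, 1].
#' @return character vector of selected isomiR ids, in selection order.
#' @export
select_top_isomirs <- function(medians, coverage = 0.99) {
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage > 1) {
    .stop_invalid("coverage must be in (0, 1]")
  }
  if (is.null(names(medians))) .stop_invalid("medians must be named by isomiR id")
  total <- sum(medians)
  if (total <= 0) {
    warning("all medians are zero; no isomiRs selected", call. = FALSE)
    return(character(0))
  }
  ord <- order(-medians, names(medians))
  cum <- cumsum(medians[ord])
  n <- which(cum >= coverage * total * (1 - 1e-12))[1]
  names(medians)[ord][seq_len(n)]
}

#' Filter transcripts with widespread zero counts
#'
#' Discards transcripts with zero counts in strictly more than half of the
#' samples; a transcript zero in exactly half is retained. The decision
#' depends only on the zero-pattern, not on magnitudes.
#'
#' @param counts features-by-samples matrix.
#' @return the retained rows of `counts`.
#' @export
filter_low_transcripts <- function(counts) {
  zeros <- rowSums(counts == 0)
  counts[zeros * 2 <= ncol(counts), , drop = FALSE]
}
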