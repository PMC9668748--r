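#' Counts per million
#'
#' @param counts a [count_matrix()] or a plain genes x samples count matrix.
#' @return genes x samples matrix of CPM values.
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  lib <- colSums(m)
  if (any(lib <= 0)) stop("empty sample: zero library size in ",
                          paste(colnames(m)[lib <= 0], collapse = ", "))
  sweep(m, 2, lib, `/`) * 1e6
}

#' Expression-level and length feature filter
#'
#' Retains genes with CPM strictly greater than `cpm_threshold` in at least
#' `ceiling(sample_fraction * n_samples)` samples, and with effective length at
#' least `min_length_bp`. Gene order is preserved; the operation is idempotent.
#'
#' @param counts a [count_matrix()].
#' @param cpm_threshold CPM cutoff (strict `>`); default 0.1.
#' @param sample_fraction fraction of samples that must pass; default 0.30.
#' @param min_length_bp minimum effective length in bp; default 15.
#' @return filtered [count_matrix()]; warns if no gene survives.
#' @export
filter_features <- function(counts, cpm_threshold = 0.1,
                            sample_fraction = 0.30, min_length_bp = 15) {
  stopifnot(inherits(counts, "count_matrix"),
            cpm_threshold > 0, sample_fraction > 0, min_length_bp > 0)
  x <- cpm(counts)
  need <- ceiling(sample_fraction * ncol(x))
  pass_cpm <- rowSums(x > cpm_threshold) >= need
  pass_len <- counts$effective_length >= min_length_bp
  keep <- pass_cpm & pass_len
  if (!any(keep)) warning("no gene passed the expression/length filter")
  count_matrix(counts$counts[keep, , drop = FALSE],
               counts$effective_length[keep])
}

#' Log2-CPM normalization
#'
#' `log2(CPM + prior)`; the prior keeps zero counts finite (a zero-CPM gene
#' maps to `log2(prior)`).
#'
#' @param counts a [count_matrix()] (typically after [filter_features()]).
#' @param prior pseudo-CPM added before the log; default 0.5.
#' @return genes x samples matrix of log2(CPM + prior) values.
#' @export
log_normalize <- function(counts, prior = 0.5) {
  stopifnot(prior > 0)
  log2(cpm(counts) + prior)
}
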