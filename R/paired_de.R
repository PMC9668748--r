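#' Subjects with both regions of a pair
#'
#' @param meta sample metadata.
#' @param pair a [pair_key()] (or list with region_a/region_b).
#' @param group diagnosis label ("control" or "case").
#' @return sorted character vector of subject ids having a sample in both
#'   regions (possibly empty).
#' @export
paired_subjects <- function(meta, pair, group) {
  m <- meta[meta$diagnosis == group, ]
  a <- unique(m$subject_id[m$region == pair$region_a])
  b <- unique(m$subject_id[m$region == pair$region_b])
  sort(intersect(a, b))
}

# genes x subjects matrix of paired differences expr(region_b) - expr(region_a)
paired_diff_matrix <- function(expr, meta, pair, subjects) {
  key <- paste(meta$subject_id, meta$region)
  col_a <- match(paste(subjects, pair$region_a), key)
  col_b <- match(paste(subjects, pair$region_b), key)
  if (anyNA(col_a) || anyNA(col_b)) stop("subject lacks a region of the pair")
  d <- expr[, col_b, drop = FALSE] - expr[, col_a, drop = FALSE]
  colnames(d) <- subjects
  d
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on a vector of paired differences. Zero differences are
#' dropped before ranking; midranks are used for tied magnitudes. With at most
#' `exact_limit` nonzero differences the p-value comes from the exact
#' (tie-aware) null distribution of the signed-rank statistic, equivalent to
#' enumerating all sign assignments; above that, a normal approximation with
#' continuity and tie correction is used. With no nonzero difference p = 1.
#'
#' @param diffs numeric vector of paired differences (finite).
#' @param exact_limit maximum number of nonzero pairs for the exact null
#'   (default 25).
#' @return two-sided p-value in (0, 1\].
#' @export
signed_rank_test <- function(diffs, exact_limit = 25) {
  if (any(!is.finite(diffs))) stop("non-finite paired differences")
  as.numeric(.cpp_signed_rank_p(matrix(diffs, nrow = 1), exact_limit))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotone enforcement (wraps
#' `stats::p.adjust(method = "BH")`); rejects missing p-values.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("NA/NaN p-values are not allowed")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Count differentially expressed genes between two regions in one group
#'
#' The primitive of the regional-identity analysis: per gene, within-subject
#' paired differences between the two regions are tested with the paired
#' Wilcoxon signed-rank test across all subjects of the group possessing both
#' regions; p-values are BH-adjusted across genes; genes with q < `alpha` are
#' counted as differentially expressed.
#'
#' @param expr genes x samples (regressed) log-expression matrix.
#' @param meta aligned metadata.
#' @param pair a [pair_key()].
#' @param group diagnosis label.
#' @param alpha FDR threshold (default 0.05).
#' @param exact_limit passed to [signed_rank_test()].
#' @return object of class `de_result`: list with `pair`, `group`,
#'   `subjects`, `n_subjects`, per-gene `table` (gene_id, p, q, direction,
#'   de_flag) and `n_de`. `direction` is the sign of the median paired
#'   difference (region_b minus region_a).
#' @export
count_de <- function(expr, meta, pair, group, alpha = 0.05, exact_limit = 25) {
  subjects <- paired_subjects(meta, pair, group)
  if (length(subjects) < 2)
    stop("infeasible comparison: fewer than 2 subjects with both regions (",
         pair$pair, ", ", group, ")")
  d <- paired_diff_matrix(expr, meta, pair, subjects)
  p <- as.numeric(.cpp_signed_rank_p(d, exact_limit))
  q <- bh_adjust(p)
  med <- apply(d, 1, stats::median)
  tab <- data.frame(gene_id = rownames(expr), p = p, q = q,
                    direction = sign(med), de_flag = q < alpha,
                    stringsAsFactors = FALSE)
  structure(list(pair = pair, group = group, subjects = subjects,
                 n_subjects = length(subjects), alpha = alpha,
                 table = tab, n_de = sum(tab$de_flag)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result %s [%s]: %d/%d genes DE at q < %g (n = %d subjects)\n",
              x$pair$pair, x$group, x$n_de, nrow(x$table), x$alpha,
              x$n_subjects))
  invisible(x)
}

# fast DE-count on a precomputed paired-difference matrix (used internally by
# the permutation and bootstrap engines via column-index resampling)
de_count_columns <- function(d, idx, alpha, exact_limit = 25,
                             occurrence = FALSE) {
  storage.mode(idx) <- "integer"
  .cpp_de_counts(d, idx, alpha, exact_limit, occurrence)
}
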