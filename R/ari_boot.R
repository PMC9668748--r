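#' Age-matched subject subset
#'
#' Keeps the `k` subjects whose ages are closest to the median age of all
#' available subjects; ties are broken by sorted subject id, so the result is
#' deterministic.
#'
#' @param subjects data.frame with columns `subject_id` and `age` (one row per
#'   subject), or a named numeric vector of ages.
#' @param k subset size (default 10).
#' @return sorted character vector of `k` subject ids.
#' @export
age_matched_subset <- function(subjects, k = 10) {
  if (is.numeric(subjects)) {
    subjects <- data.frame(subject_id = names(subjects), age = unname(subjects),
                           stringsAsFactors = FALSE)
  }
  if (nrow(subjects) < k)
    stop("infeasible pair: fewer than ", k, " subjects available")
  med <- stats::median(subjects$age)
  ord <- order(abs(subjects$age - med), subjects$subject_id)
  sort(subjects$subject_id[ord][seq_len(k)])
}

#' Bootstrap distribution of the between-region DE count in one group
#'
#' Resamples the given subjects with replacement `B` times; duplicated
#' subjects contribute duplicated paired-difference columns; each draw is
#' scored with the same paired-Wilcoxon/BH DE count as [count_de()].
#'
#' @param expr,meta,pair as in [count_de()].
#' @param group_subjects the (age-matched) subject ids to resample.
#' @param B number of bootstrap draws (default 10000).
#' @param alpha FDR threshold (default 0.05).
#' @param seed integer seed.
#' @param exact_limit passed to the signed-rank engine.
#' @return integer vector of length `B` of DE counts.
#' @export
bootstrap_counts <- function(expr, meta, pair, group_subjects, B = 10000,
                             alpha = 0.05, seed = 1L, exact_limit = 25) {
  d <- paired_diff_matrix(expr, meta, pair, group_subjects)
  k <- length(group_subjects)
  set.seed(seed)
  idx <- matrix(sample.int(k, B * k, replace = TRUE), nrow = B)
  as.integer(de_count_columns(d, idx, alpha, exact_limit)$counts)
}

#' Bootstrap attenuation test across region pairs
#'
#' For each pair: subset each diagnosis group to `k` age-matched subjects
#' possessing both regions (making DE counts comparable across pairs with
#' unequal cohort sizes), bootstrap the between-region DE count `B` times per
#' group, and compare the control and case count distributions with a
#' two-sample Wilcoxon (Mann-Whitney) test. P-values are BH-adjusted across
#' the tested pairs; a pair is `attenuated` when q < `alpha_class` and the
#' median case count is below the median control count. Identical count
#' distributions in both groups give p = 1.
#'
#' Each (pair, group) draws from an independent seed stream derived from the
#' master seed, so adding or dropping pairs never perturbs the others.
#'
#' @param expr genes x samples (regressed) log-expression matrix.
#' @param meta aligned metadata (must carry `age`).
#' @param pairs data.frame from [region_pairs()].
#' @param regions ordered region vector.
#' @param k age-matched subset size per group (default 10).
#' @param B bootstrap draws per group (default 10000).
#' @param alpha per-gene FDR threshold inside the DE counts (default 0.05).
#' @param alpha_class FDR threshold on the pair-level tests (default 0.05).
#' @param seed master seed.
#' @param exact_limit passed to the signed-rank engine.
#' @return object of class `ari_boot`: list with `summary` data.frame (pair,
#'   median_control, median_case, mw_p, q, attenuated) and `counts` (per pair,
#'   list of control/case bootstrap count vectors).
#' @export
bootstrap_ari <- function(expr, meta, pairs = region_pairs(),
                          regions = default_regions(), k = 10, B = 10000,
                          alpha = 0.05, alpha_class = 0.05, seed = 1L,
                          exact_limit = 25) {
  ages <- meta[!duplicated(meta$subject_id), c("subject_id", "age")]
  counts <- vector("list", nrow(pairs))
  names(counts) <- pairs$pair
  mw_p <- med_c <- med_a <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pk <- pair_key(pairs$region_a[i], pairs$region_b[i], regions)
    per_group <- lapply(c(control = "control", case = "case"), function(grp) {
      subj <- paired_subjects(meta, pk, grp)
      subj <- age_matched_subset(ages[ages$subject_id %in% subj, ], k)
      bootstrap_counts(expr, meta, pk, subj, B = B, alpha = alpha,
                       seed = derive_seed(seed, paste(pk$pair, grp)),
                       exact_limit = exact_limit)
    })
    counts[[i]] <- per_group
    med_c[i] <- stats::median(per_group$control)
    med_a[i] <- stats::median(per_group$case)
    all_vals <- c(per_group$control, per_group$case)
    mw_p[i] <- if (length(unique(all_vals)) == 1L) 1 else
      suppressWarnings(stats::wilcox.test(per_group$control,
                                          per_group$case)$p.value)
  }
  q <- bh_adjust(mw_p)
  summary <- data.frame(pair = pairs$pair, median_control = med_c,
                        median_case = med_a, mw_p = mw_p, q = q,
                        attenuated = q < alpha_class & med_a < med_c,
                        stringsAsFactors = FALSE)
  structure(list(summary = summary, counts = counts, k = k, B = B,
                 seed = seed, alpha = alpha),
            class = "ari_boot")
}

#' @export
print.ari_boot <- function(x, ...) {
  cat(sprintf("ari_boot: %d pairs, %d attenuated (k = %d, B = %d)\n",
              nrow(x$summary), sum(x$summary$attenuated), x$k, x$B))
  invisible(x)
}
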