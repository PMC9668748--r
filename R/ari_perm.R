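#' Permute diagnosis labels at the subject level
#'
#' Uniformly random partition of the pooled subjects into pseudo-case and
#' pseudo-control groups preserving the true group sizes.
#'
#' @param subjects_case,subjects_control disjoint character vectors.
#' @param seed integer seed.
#' @return list with `case` and `control` character vectors.
#' @export
permute_labels <- function(subjects_case, subjects_control, seed) {
  if (length(intersect(subjects_case, subjects_control)))
    stop("case and control subject lists overlap")
  if (!length(subjects_case) || !length(subjects_control))
    stop("both groups must be nonempty")
  set.seed(seed)
  pool <- c(subjects_case, subjects_control)
  pick <- sample.int(length(pool), length(subjects_case))
  list(case = pool[pick], control = pool[-pick])
}

# B x n_case and B x n_ctrl matrices of column indices into the pooled
# paired-difference matrix; the shared permutation stream for ari_test() and
# permutation_occurrence(). enumerate = TRUE replaces the Monte-Carlo stream
# with all choose(n, n_case) equal-size assignments (B ignored).
make_permutations <- function(n_case, n_ctrl, B, seed, enumerate = FALSE) {
  n <- n_case + n_ctrl
  if (enumerate) {
    cs <- utils::combn(n, n_case)
    case_idx <- t(cs)
    ctrl_idx <- t(apply(cs, 2, function(s) setdiff(seq_len(n), s)))
    if (n_ctrl == 1) ctrl_idx <- matrix(ctrl_idx, ncol = 1)
  } else {
    set.seed(seed)
    case_idx <- matrix(0L, B, n_case)
    ctrl_idx <- matrix(0L, B, n_ctrl)
    for (b in seq_len(B)) {
      pick <- sample.int(n, n_case)
      case_idx[b, ] <- pick
      ctrl_idx[b, ] <- setdiff(seq_len(n), pick)
    }
  }
  list(case = case_idx, control = ctrl_idx)
}

#' Permutation test for attenuation of regional identity at one region pair
#'
#' Computes the true difference `n_de(case) - n_de(control)` in paired-Wilcoxon
#' DE counts between the two regions, then rebuilds its null distribution by
#' randomly reassigning diagnosis labels to subjects (group sizes preserved) B
#' times and recomputing both counts under identical tie and FDR rules. The
#' two-tailed p-value uses the add-one estimator
#' `p = (1 + #{|perm| >= |true|}) / (B + 1)`. A pair is classified
#' `attenuated` when p < `alpha_class` and the case count is lower,
#' `over_patterned` when p < `alpha_class` and the case count is higher, and
#' `not_significant` otherwise.
#'
#' Only subjects possessing both regions enter; the per-subject paired
#' differences do not depend on the diagnosis labels, so they are computed once
#' and permutations only repartition subject columns.
#'
#' @param expr genes x samples (regressed) log-expression matrix.
#' @param meta aligned metadata.
#' @param pair a [pair_key()].
#' @param B number of permutations (default 10000).
#' @param alpha per-gene FDR threshold inside each DE count (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @param alpha_class significance level for the classification (default 0.05).
#' @param exact_limit passed to the signed-rank engine.
#' @param enumerate if `TRUE`, use all equal-size label assignments instead of
#'   B Monte-Carlo draws (exact permutation p; feasible for small cohorts).
#' @return object of class `ari_perm`: list with `pair`, `n_de_control`,
#'   `n_de_case`, `true_diff`, `perm_diffs`, `p`, `classification`, `B`,
#'   `seed`, and the subject lists used.
#' @export
ari_test <- function(expr, meta, pair, B = 10000, alpha = 0.05, seed = 1L,
                     alpha_class = 0.05, exact_limit = 25, enumerate = FALSE) {
  subj_case <- paired_subjects(meta, pair, "case")
  subj_ctrl <- paired_subjects(meta, pair, "control")
  if (length(subj_case) < 2 || length(subj_ctrl) < 2)
    stop("infeasible pair: fewer than 2 paired subjects in a group (",
         pair$pair, ")")

  pooled <- c(subj_case, subj_ctrl)
  d <- paired_diff_matrix(expr, meta, pair, pooled)
  n_case <- length(subj_case); n_ctrl <- length(subj_ctrl)

  true_case <- de_count_columns(d, matrix(seq_len(n_case), 1), alpha,
                                exact_limit)$counts
  true_ctrl <- de_count_columns(d, matrix(n_case + seq_len(n_ctrl), 1), alpha,
                                exact_limit)$counts
  true_diff <- true_case - true_ctrl

  perms <- make_permutations(n_case, n_ctrl, B, seed, enumerate)
  perm_case <- de_count_columns(d, perms$case, alpha, exact_limit)$counts
  perm_ctrl <- de_count_columns(d, perms$control, alpha, exact_limit)$counts
  perm_diffs <- perm_case - perm_ctrl
  Bp <- length(perm_diffs)

  p <- (1 + sum(abs(perm_diffs) >= abs(true_diff))) / (Bp + 1)
  classification <- if (p < alpha_class && true_case < true_ctrl) {
    "attenuated"
  } else if (p < alpha_class && true_case > true_ctrl) {
    "over_patterned"
  } else "not_significant"

  structure(list(pair = pair, n_de_control = true_ctrl, n_de_case = true_case,
                 true_diff = true_diff, perm_diffs = perm_diffs, p = p,
                 classification = classification, B = Bp, seed = seed,
                 alpha = alpha, subjects_case = subj_case,
                 subjects_control = subj_ctrl, enumerate = enumerate),
            class = "ari_perm")
}

#' @export
print.ari_perm <- function(x, ...) {
  cat(sprintf(
    "ari_perm %s: n_de control = %d, case = %d, true diff = %d, p = %.4g (%s, B = %d)\n",
    x$pair$pair, x$n_de_control, x$n_de_case, x$true_diff, x$p,
    x$classification, x$B))
  invisible(x)
}

#' Run the permutation attenuation test over many region pairs
#'
#' @param expr,meta as in [ari_test()].
#' @param pairs data.frame from [region_pairs()] (or subset thereof).
#' @param regions ordered region vector for canonical pair keys.
#' @param ... passed to [ari_test()] (B, alpha, exact_limit, ...).
#' @param seed master seed; each pair gets an independent stream derived from
#'   it, so adding a pair never perturbs the others.
#' @return list with `summary` data.frame (pair, n_de_control, n_de_case,
#'   true_diff, p, classification) and `outcomes` (named list of `ari_perm`
#'   objects).
#' @export
ari_test_all <- function(expr, meta, pairs = region_pairs(),
                         regions = default_regions(), seed = 1L, ...) {
  outcomes <- lapply(seq_len(nrow(pairs)), function(i) {
    pk <- pair_key(pairs$region_a[i], pairs$region_b[i], regions)
    ari_test(expr, meta, pk, seed = derive_seed(seed, pk$pair), ...)
  })
  names(outcomes) <- pairs$pair
  summary <- data.frame(
    pair = pairs$pair,
    n_de_control = vapply(outcomes, function(o) as.integer(o$n_de_control), 1L),
    n_de_case = vapply(outcomes, function(o) as.integer(o$n_de_case), 1L),
    true_diff = vapply(outcomes, function(o) as.integer(o$true_diff), 1L),
    p = vapply(outcomes, function(o) o$p, 1.0),
    classification = vapply(outcomes, function(o) o$classification, ""),
    stringsAsFactors = FALSE)
  list(summary = summary, outcomes = outcomes)
}
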