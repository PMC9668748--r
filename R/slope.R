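#' Case-versus-control log2 fold change per gene
#'
#' Simple subject-balanced contrast on (regressed) log expression: per gene,
#' each subject's in-scope samples are averaged first, then the mean over case
#' subjects minus the mean over control subjects is returned. `scope` selects
#' one region or `"whole_cortex"` (all samples).
#'
#' @param expr genes x samples (regressed) log2 expression matrix.
#' @param meta aligned metadata.
#' @param scope a region label or `"whole_cortex"`.
#' @return named numeric vector of per-gene log2 fold changes (case - control).
#' @export
compute_log2fc <- function(expr, meta, scope = "whole_cortex") {
  sel <- if (identical(scope, "whole_cortex")) rep(TRUE, nrow(meta))
         else meta$region == scope
  m <- meta[sel, ]
  if (!all(c("control", "case") %in% m$diagnosis))
    stop("scope '", scope, "' lacks a diagnosis group")
  x <- expr[, sel, drop = FALSE]
  group_mean <- function(grp) {
    subj <- unique(m$subject_id[m$diagnosis == grp])
    per_subj <- vapply(subj, function(s) {
      rowMeans(x[, m$subject_id == s & m$diagnosis == grp, drop = FALSE])
    }, numeric(nrow(x)))
    rowMeans(matrix(per_subj, nrow = nrow(x)))
  }
  fc <- group_mean("case") - group_mean("control")
  stats::setNames(fc, rownames(expr))
}

#' Total least squares (orthogonal) regression slope
#'
#' Line fit minimizing the summed squared perpendicular distances of the
#' centered (x, y) cloud: the slope is the direction of the leading eigenvector
#' of the 2x2 covariance matrix, with the sign of the covariance. Unlike
#' ordinary least squares it is invariant to which variable is treated as the
#' predictor (swapping x and y returns the reciprocal slope), which matters
#' when both effect-size vectors are estimated with error.
#'
#' @param x,y numeric vectors of equal length (>= 3); if named, they are
#'   matched on shared names first.
#' @return list with `slope`, `intercept`, `n`.
#' @export
tls_slope <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  if (length(x) != length(y)) stop("x and y must pair up")
  if (length(x) < 3) stop("need at least 3 shared observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite effect sizes")
  mx <- mean(x); my <- mean(y)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0) stop("degenerate cloud: zero variance")
  slope <- if (sxy != 0) {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  } else if (sxx > syy) {
    0
  } else {
    stop("degenerate fit: principal axis is vertical (infinite slope)")
  }
  if (sxy != 0 && sign(slope) != sign(sxy))
    slope <- -1 / slope   # guard; analytic root already matches cov sign
  list(slope = slope, intercept = my - slope * mx, n = length(x))
}

#' Bootstrap inference for the orthogonal-regression slope
#'
#' Resamples the genes (the observations of the effect-size cloud) with
#' replacement, recomputes the TLS slope per draw, and reports the percentile
#' 95% CI plus a two-sided bootstrap p-value against slope = 1,
#' `p = 2 * min(frac(boot <= 1), frac(boot >= 1))` floored at
#' `2 / (n_boot + 1)`. Degenerate resamples are skipped and counted; more than
#' 10% skipped aborts.
#'
#' @param x,y effect-size vectors as in [tls_slope()].
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @return object of class `slope_fit`: list with `slope`, `intercept`,
#'   `ci` (2.5/97.5 percentiles), `p_vs_unity`, `n_boot`, `n_genes`,
#'   `n_skipped`, `seed`, and the bootstrap slopes.
#' @export
slope_bootstrap <- function(x, y, n_boot = 1000, seed = 1L) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  fit <- tls_slope(x, y)
  n <- length(x)
  set.seed(seed)
  boots <- numeric(n_boot)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    s <- tryCatch(tls_slope(unname(x[idx]), unname(y[idx]))$slope,
                  error = function(e) NA_real_)
    if (is.na(s)) skipped <- skipped + 1L
    boots[b] <- s
  }
  if (skipped > 0.1 * n_boot)
    stop("more than 10% of bootstrap resamples were degenerate (",
         skipped, "/", n_boot, ")")
  bs <- boots[!is.na(boots)]
  ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  p <- 2 * min(mean(bs <= 1), mean(bs >= 1))
  p <- min(1, max(p, 2 / (n_boot + 1)))
  structure(list(slope = fit$slope, intercept = fit$intercept, ci = ci,
                 p_vs_unity = p, n_boot = n_boot, n_genes = n,
                 n_skipped = skipped, seed = seed, boot_slopes = boots),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope_fit: S = %.4f [%.4f, %.4f], p (S != 1) = %.4g, n = %d genes\n",
              x$slope, x$ci[1], x$ci[2], x$p_vs_unity, x$n_genes))
  invisible(x)
}
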