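#' Biweight midcorrelation
#'
#' Robust correlation between the columns of `x`: observations are weighted by
#' `(1 - u^2)^2` for `|u| < 1`, with `u = (x - median) / (9 * MAD)` (unscaled
#' MAD). Columns with zero MAD fall back to Pearson centering (mean, ordinary
#' deviations), the conventional fallback.
#'
#' @param x numeric matrix; correlations are between columns.
#' @return symmetric correlation matrix; `NA` where a column is constant.
#' @export
bicor <- function(x) {
  n <- ncol(x)
  w <- matrix(0, nrow(x), n)
  dev <- matrix(0, nrow(x), n)
  for (j in seq_len(n)) {
    v <- x[, j]
    med <- stats::median(v)
    m <- stats::mad(v, constant = 1)
    if (m > 0) {
      u <- (v - med) / (9 * m)
      wj <- (1 - u^2)^2 * (abs(u) < 1)
      dev[, j] <- (v - med) * wj
    } else if (stats::sd(v) > 0) {
      dev[, j] <- v - mean(v)       # Pearson fallback
    } else {
      dev[, j] <- NA_real_          # constant column: undefined
    }
    norm <- sqrt(sum(dev[, j]^2))
    dev[, j] <- dev[, j] / norm
  }
  out <- crossprod(dev)
  dimnames(out) <- list(colnames(x), colnames(x))
  out
}

#' Sample outlier detection by expression PCs and network connectivity
#'
#' Within each QC group (by default sequencing batch crossed with cortical
#' lobe), a sample is flagged as an outlier when it is extreme on BOTH
#' criteria: (1) absolute z-score above `z_pc` on any of the top `n_pcs`
#' expression principal components of the gene-centered matrix, and (2)
#' standardized network connectivity `Z.k` below `z_k`, where connectivity is
#' the row sum (self excluded) of the signed adjacency
#' `((1 + bicor) / 2)^soft_power` between samples.
#'
#' Groups with fewer than 5 samples are skipped with a warning. If all samples
#' in a group are identical the connectivity SD is zero, `Z.k` is undefined and
#' nothing is flagged. A constant (degenerate) sample makes its correlations
#' undefined; it is marked `degenerate = TRUE` for manual review, never
#' silently dropped.
#'
#' @param expr genes x samples log-expression matrix.
#' @param meta aligned sample metadata; `batch` is used if present.
#' @param group_by character vector of metadata column names forming the QC
#'   group; `"lobe"` is derived from `region` via [region_lobe()]. Defaults to
#'   batch x lobe, or lobe alone when no batch column exists.
#' @param z_pc PC |z| threshold (default 3).
#' @param z_k connectivity z threshold (default -2).
#' @param n_pcs number of top PCs examined (default 10).
#' @param soft_power adjacency soft power (default 2).
#' @return data.frame (one row per sample): `sample_id`, `group`,
#'   `max_abs_pc_z`, `z_k`, `outlier`, `degenerate`. Samples in skipped groups
#'   get `NA` statistics and `outlier = FALSE`.
#' @export
detect_outliers <- function(expr, meta, group_by = NULL, z_pc = 3, z_k = -2,
                            n_pcs = 10, soft_power = 2) {
  check_alignment(expr, meta)
  meta$lobe <- region_lobe(meta$region)
  if (is.null(group_by)) {
    group_by <- if ("batch" %in% names(meta)) c("batch", "lobe") else "lobe"
  }
  grp <- interaction(meta[group_by], drop = TRUE, sep = ":")

  out <- data.frame(sample_id = meta$sample_id, group = as.character(grp),
                    max_abs_pc_z = NA_real_, z_k = NA_real_,
                    outlier = FALSE, degenerate = FALSE,
                    stringsAsFactors = FALSE)

  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 5) {
      warning("QC group '", g, "' has < 5 samples; skipped")
      next
    }
    x <- expr[, idx, drop = FALSE]
    constant <- apply(x, 2, stats::sd) == 0
    if (any(constant)) {
      out$degenerate[idx[constant]] <- TRUE
      warning("degenerate (constant) sample(s) in group '", g,
              "': ", paste(meta$sample_id[idx[constant]], collapse = ", "),
              "; flagged for manual review")
    }

    # (1) PC criterion on the gene-centered matrix
    xc <- x - rowMeans(x)
    pc <- stats::prcomp(t(xc), center = FALSE)
    k <- min(n_pcs, ncol(pc$x), sum(pc$sdev > 1e-12))
    if (k >= 1) {
      z <- scale(pc$x[, seq_len(k), drop = FALSE])
      out$max_abs_pc_z[idx] <- apply(abs(z), 1, max)
    }

    # (2) connectivity criterion
    ok <- !constant
    if (sum(ok) >= 3) {
      a <- ((1 + bicor(x[, ok, drop = FALSE])) / 2)^soft_power
      conn <- rowSums(a) - diag(a)
      s <- stats::sd(conn)
      if (is.finite(s) && s > 0) {
        out$z_k[idx[ok]] <- (conn - mean(conn)) / s
      }
    }

    flag <- !is.na(out$max_abs_pc_z[idx]) & out$max_abs_pc_z[idx] > z_pc &
      !is.na(out$z_k[idx]) & out$z_k[idx] < z_k
    out$outlier[idx] <- flag
  }
  out
}
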