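#' Remove nuisance covariate effects, keeping subject, diagnosis and region
#'
#' Per gene, fits a linear mixed model with a subject random intercept and
#' fixed effects for diagnosis, region and every nuisance covariate, then
#' subtracts only the nuisance fixed-effect contributions. The result retains
#' the subject random effect, the diagnosis and region effects and the
#' residual — the working matrix for all regional-identity statistics. With an
#' empty nuisance set the operation is the identity.
#'
#' Genes whose mixed-model fit fails to converge are refit by ordinary least
#' squares (same fixed effects, no random intercept) and recorded in the
#' `fallback_genes` attribute.
#'
#' @param expr genes x samples log-expression matrix.
#' @param meta aligned metadata; columns other than sample_id, subject_id,
#'   region, diagnosis are treated as nuisance covariates unless `nuisance` is
#'   given explicitly.
#' @param nuisance character vector of metadata columns to remove; `NULL`
#'   auto-detects. Columns named but absent are skipped with a message.
#' @return matrix of regressed expression, same shape as `expr`, with
#'   attributes `removed_covariates` and `fallback_genes`.
#' @export
regress_covariates <- function(expr, meta, nuisance = NULL) {
  check_alignment(expr, meta)
  if (length(unique(meta$subject_id[meta$diagnosis == "control"])) < 2 ||
      length(unique(meta$subject_id[meta$diagnosis == "case"])) < 2)
    stop("need >= 2 subjects per diagnosis group")

  reserved <- c("sample_id", "subject_id", "region", "diagnosis")
  if (is.null(nuisance)) {
    nuisance <- setdiff(names(meta), c(reserved, "lobe"))
  } else {
    missing <- setdiff(nuisance, names(meta))
    if (length(missing)) {
      message("nuisance covariate(s) absent and skipped: ",
              paste(missing, collapse = ", "))
      nuisance <- intersect(nuisance, names(meta))
    }
  }
  # drop covariates with a single level (nothing to remove)
  nuisance <- nuisance[vapply(nuisance, function(v) {
    length(unique(meta[[v]])) > 1L
  }, logical(1))]

  if (!length(nuisance)) {
    out <- expr
    attr(out, "removed_covariates") <- character(0)
    attr(out, "fallback_genes") <- character(0)
    return(out)
  }

  df <- meta
  df$region <- factor(df$region)
  df$diagnosis <- factor(df$diagnosis)
  for (v in nuisance) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])

  fixed_rhs <- paste(c("diagnosis", "region", nuisance), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), df)
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: collinear covariate column(s) among ",
         paste(nuisance, collapse = ", "))
  }
  # nuisance columns of the fixed-effect design
  asgn <- attr(X, "assign")
  term_labels <- attr(stats::terms(stats::as.formula(paste("~", fixed_rhs))),
                      "term.labels")
  nuis_cols <- which(asgn > 0 & term_labels[pmax(asgn, 1)] %in% nuisance)

  form <- stats::as.formula(paste("y ~", fixed_rhs, "+ (1 | subject_id)"))
  out <- expr
  fallback <- character(0)
  for (g in seq_len(nrow(expr))) {
    df$y <- expr[g, ]
    beta <- tryCatch({
      fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE))
      # a boundary (singular) fit — zero subject variance — is a valid
      # estimate; only genuine optimizer failures trigger the OLS fallback
      msgs <- fit@optinfo$conv$lme4$messages
      bad <- msgs[!grepl("boundary \\(singular\\)", msgs)]
      if (length(bad) || !is.null(fit@optinfo$conv$opt) &&
          fit@optinfo$conv$opt != 0) stop("non-convergence")
      lme4::fixef(fit)
    }, error = function(e) NULL)
    if (is.null(beta)) {
      fallback <- c(fallback, rownames(expr)[g])
      beta <- stats::coef(stats::lm(df$y ~ X - 1))
      names(beta) <- colnames(X)
    }
    beta <- beta[colnames(X)]
    beta[is.na(beta)] <- 0
    out[g, ] <- expr[g, ] - as.vector(X[, nuis_cols, drop = FALSE] %*%
                                        beta[nuis_cols])
  }
  attr(out, "removed_covariates") <- nuisance
  attr(out, "fallback_genes") <- fallback
  out
}
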