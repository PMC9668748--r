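#' Simulation configuration for a synthetic multi-region cohort
#'
#' Defines the generative model for a case/control cohort sampled across
#' cortical regions. Expression is simulated on the log2 scale as
#' \deqn{x_{gsr} = \mu + u_s + \beta_g \, r(\mathrm{region}) \, \lambda^{[case]}
#'   + \mathrm{covariates} + \varepsilon,\quad \varepsilon \sim N(0, \sigma^2),}
#' where a fraction of genes carry an anterior-to-posterior gradient slope
#' \eqn{\beta_g} (log2 units per rank step), subjects have random intercepts
#' \eqn{u_s}, and in case subjects all gradient slopes are multiplied by the
#' attenuation factor \eqn{\lambda \in [0, 1]} (1 = null, 0 = gradients fully
#' erased). Each subject contributes at most one sample per region; regions are
#' dropped independently per subject with probability `missing_rate`.
#'
#' @param n_control,n_case subjects per group (each >= 2).
#' @param regions ordered region labels, anterior first; rank = position.
#' @param missing_rate probability in \[0, 1) that a subject lacks a region.
#' @param n_genes number of genes.
#' @param gradient_fraction fraction of genes given a nonzero gradient slope.
#' @param gradient_effect_sd SD of the per-gene gradient slope (log2/rank step).
#' @param subject_sd SD of the subject random intercept (log2 units).
#' @param noise_sd residual SD (log2 units).
#' @param attenuation multiplicative factor on gradient slopes in cases.
#' @param covariate_effects optional named list mapping a nuisance covariate
#'   ("batch", "sex", "age") to the SD of its per-gene effect size.
#' @param emit_counts if `TRUE`, [emit_counts()] may be used on the result.
#' @param nb_dispersion negative-binomial size (inverse-overdispersion) for
#'   count emission; variance = mu + mu^2 / nb_dispersion, so large values
#'   approach the Poisson limit.
#' @param mean_log_expr baseline mean log2 expression.
#' @param n_batches number of sequencing batches sampled per sample.
#' @param seed integer seed; identical configs + seed give bit-identical data.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_control = 15, n_case = 15,
                              regions = default_regions(),
                              missing_rate = 0.3,
                              n_genes = 2000,
                              gradient_fraction = 0.25,
                              gradient_effect_sd = 0.2,
                              subject_sd = 0.5,
                              noise_sd = 0.5,
                              attenuation = 1,
                              covariate_effects = NULL,
                              emit_counts = FALSE,
                              nb_dispersion = 10,
                              mean_log_expr = 4,
                              n_batches = 2,
                              seed = 1L) {
  cfg <- list(n_control = n_control, n_case = n_case, regions = regions,
              missing_rate = missing_rate, n_genes = n_genes,
              gradient_fraction = gradient_fraction,
              gradient_effect_sd = gradient_effect_sd,
              subject_sd = subject_sd, noise_sd = noise_sd,
              attenuation = attenuation, covariate_effects = covariate_effects,
              emit_counts = emit_counts, nb_dispersion = nb_dispersion,
              mean_log_expr = mean_log_expr, n_batches = n_batches,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_control < 2 || n_case < 2) stop("need >= 2 subjects per group")
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
    if (gradient_fraction < 0 || gradient_fraction > 1) stop("gradient_fraction must be in [0, 1]")
    if (attenuation < 0 || attenuation > 1) stop("attenuation must be in [0, 1]")
    if (anyDuplicated(regions)) stop("regions must be unique")
    if (any(c(gradient_effect_sd, subject_sd, noise_sd) < 0)) stop("SDs must be >= 0")
    if (n_genes < 1) stop("n_genes must be positive")
    if (emit_counts && nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  })
  invisible(cfg)
}

#' Generate a synthetic multi-region expression cohort
#'
#' Draws a cohort under the model described in [simulation_config()]. Missing
#' (subject, region) combinations are dropped; the design is rejected as
#' infeasible if any region is left with fewer than 2 subjects in either group
#' (downstream paired tests would be undefined).
#'
#' @param config a [simulation_config()].
#' @return list with components
#'   \item{expr}{genes x samples matrix of log2 expression, dimnames set;}
#'   \item{meta}{data.frame with sample_id, subject_id, region, diagnosis
#'     ("control"/"case"), age, sex, batch — rows aligned to `expr` columns;}
#'   \item{truth}{list: `gradient_gene_ids`, `per_gene_slope` (named vector),
#'     `subject_intercepts` (named vector), `expected_attenuated_pairs`
#'     (character pair keys with expected negative case-minus-control DE-count
#'     difference, i.e. all pairs when attenuation < 1 and gradients exist).}
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  regions <- config$regions
  n_reg <- length(regions)

  subjects <- c(sprintf("ctl%02d", seq_len(config$n_control)),
                sprintf("case%02d", seq_len(config$n_case)))
  diagnosis <- rep(c("control", "case"), c(config$n_control, config$n_case))
  names(diagnosis) <- subjects

  age <- stats::runif(length(subjects), 10, 60)
  sex <- sample(c("M", "F"), length(subjects), replace = TRUE)
  names(age) <- names(sex) <- subjects

  # region availability per subject
  keep <- matrix(stats::runif(length(subjects) * n_reg) >= config$missing_rate,
                 nrow = length(subjects),
                 dimnames = list(subjects, regions))
  per_region <- sapply(regions, function(r) {
    tapply(keep[, r], diagnosis, sum)[c("control", "case")]
  })
  if (any(per_region < 2)) {
    bad <- regions[apply(per_region < 2, 2, any)]
    stop("infeasible design: region(s) ", paste(bad, collapse = ", "),
         " left with < 2 subjects in a group; lower missing_rate or add subjects")
  }

  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  n_grad <- round(config$gradient_fraction * config$n_genes)
  gradient_gene_ids <- sort(sample(gene_ids, n_grad))
  slope <- stats::setNames(numeric(config$n_genes), gene_ids)
  slope[gradient_gene_ids] <- stats::rnorm(n_grad, 0, config$gradient_effect_sd)

  u <- stats::setNames(stats::rnorm(length(subjects), 0, config$subject_sd), subjects)

  meta <- do.call(rbind, lapply(subjects, function(s) {
    rs <- regions[keep[s, ]]
    if (!length(rs)) return(NULL)
    data.frame(sample_id = paste(s, gsub("/", ".", rs), sep = "_"),
               subject_id = s, region = rs, diagnosis = diagnosis[[s]],
               age = age[[s]], sex = sex[[s]], stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  meta$batch <- paste0("b", sample.int(config$n_batches, nrow(meta), replace = TRUE))

  rank_of <- stats::setNames(seq_len(n_reg), regions)
  lambda <- ifelse(meta$diagnosis == "case", config$attenuation, 1)
  grad_term <- outer(slope, rank_of[meta$region] * lambda)  # genes x samples

  expr <- config$mean_log_expr + grad_term +
    matrix(rep(u[meta$subject_id], each = config$n_genes), nrow = config$n_genes)

  if (!is.null(config$covariate_effects)) {
    for (cov in names(config$covariate_effects)) {
      x <- switch(cov,
                  batch = as.numeric(meta$batch != "b1"),
                  sex   = as.numeric(meta$sex == "F"),
                  age   = as.numeric(scale(meta$age)),
                  stop("unsupported covariate effect: ", cov))
      beta <- stats::rnorm(config$n_genes, 0, config$covariate_effects[[cov]])
      expr <- expr + outer(beta, x)
    }
  }

  expr <- expr + matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                        nrow = config$n_genes)
  dimnames(expr) <- list(gene_ids, meta$sample_id)

  pairs <- region_pairs(regions)
  expected <- if (config$attenuation < 1 && n_grad > 0) pairs$pair else character(0)

  list(expr = expr, meta = meta,
       truth = list(gradient_gene_ids = gradient_gene_ids,
                    per_gene_slope = slope,
                    subject_intercepts = u,
                    expected_attenuated_pairs = expected))
}

#' Materialize negative-binomial counts from log expression
#'
#' Converts a log2 expression matrix into a count matrix: per-sample expected
#' counts proportional to `2^expr`, scaled to the target library size, drawn
#' from a negative binomial with size `config$nb_dispersion` (variance
#' mu + mu^2/size; large size approaches Poisson). A `-Inf` entry is a
#' structural zero and always yields count 0. Effective gene lengths are
#' attached for downstream length filtering.
#'
#' @param expr genes x samples log2 expression matrix (dimnames required).
#' @param config a [simulation_config()] with `emit_counts = TRUE`.
#' @param lib_size target library size per sample (scalar or per-sample vector).
#' @param effective_length per-gene effective length in bp (scalar recycled or
#'   named vector); default 1000.
#' @return object of class `count_matrix`: list with `counts` (integer-valued
#'   genes x samples matrix) and `effective_length` (named vector).
#' @export
emit_counts <- function(expr, config, lib_size = 1e6, effective_length = 1000) {
  if (!isTRUE(config$emit_counts)) stop("config does not enable count emission")
  if (any(is.nan(expr)) || any(expr == Inf)) {
    stop("corrupted input: expression contains NaN or +Inf")
  }
  set.seed(derive_seed(config$seed, "emit_counts"))
  mu_raw <- 2^expr                      # -Inf -> 0 exactly
  tot <- colSums(mu_raw)
  if (any(tot <= 0)) stop("sample with no expressed genes")
  lib <- rep_len(lib_size, ncol(expr))
  mu <- sweep(mu_raw, 2, lib / tot, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = config$nb_dispersion),
                   nrow = nrow(expr), dimnames = dimnames(expr))
  len <- rep_len(effective_length, nrow(expr))
  names(len) <- rownames(expr)
  count_matrix(counts, len)
}

#' Construct a count matrix container
#'
#' @param counts genes x samples matrix of nonnegative counts with dimnames.
#' @param effective_length per-gene effective length (bp), named or recycled.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, effective_length = 1000) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts need gene and sample dimnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and sample ids must be unique")
  if (any(counts < 0)) stop("counts must be nonnegative")
  len <- rep_len(effective_length, nrow(counts))
  if (is.null(names(len))) names(len) <- rownames(counts)
  if (any(len <= 0)) stop("effective lengths must be positive")
  structure(list(counts = counts, effective_length = len[rownames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}
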