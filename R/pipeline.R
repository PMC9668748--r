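#' Pipeline run configuration
#'
#' One master seed drives every stage; each stage (and each region pair inside
#' a stage) derives its own stream deterministically from it, so reruns with
#' the same config reproduce all seeded outputs bit-identically and toggling a
#' stage never perturbs the others.
#'
#' @param sim a [simulation_config()] (the pipeline simulates its input), or
#'   `NULL` with `expr`/`meta` given.
#' @param expr,meta optional pre-existing log-expression matrix and aligned
#'   metadata (used when `sim` is `NULL`).
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed.
#' @param alpha per-gene FDR threshold in all DE counts.
#' @param B_perm,B_boot permutation / bootstrap draws.
#' @param k bootstrap age-matched subset size.
#' @param occurrence_threshold ARI-gene occurrence cutoff.
#' @param slope_region region contrasted against the whole cortex in the
#'   effect-size slope stage (default the most posterior region).
#' @param stages named logical vector enabling stages: simulate, qc, regress,
#'   pairwise_de, ari_perm, ari_boot, ari_genes, slope.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), expr = NULL, meta = NULL,
                       out_dir = tempfile("ari_run_"), seed = 1L,
                       alpha = 0.05, B_perm = 1000, B_boot = 1000, k = 10,
                       occurrence_threshold = 0.95, slope_region = NULL,
                       stages = c(simulate = TRUE, qc = FALSE, regress = TRUE,
                                  pairwise_de = TRUE, ari_perm = TRUE,
                                  ari_boot = TRUE, ari_genes = TRUE,
                                  slope = TRUE)) {
  structure(list(sim = sim, expr = expr, meta = meta, out_dir = out_dir,
                 seed = as.integer(seed), alpha = alpha, B_perm = B_perm,
                 B_boot = B_boot, k = k,
                 occurrence_threshold = occurrence_threshold,
                 slope_region = slope_region, stages = stages),
            class = "run_config")
}

#' Run the attenuation-of-regional-identity pipeline
#'
#' Executes the enabled stages in order — simulate, covariate regression,
#' pairwise DE counting, permutation attenuation test, bootstrap attenuation
#' test, ARI gene extraction, effect-size slope — writing each stage's tables
#' as TSV/JSON under `config$out_dir` plus a JSON manifest recording package
#' version, seeds, input checksums and stage wall-times. A stage failure stops
#' the run naming the stage; artifacts of completed stages are retained.
#'
#' @param config a [run_config()].
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(package_version = as.character(utils::packageVersion("cortexARI")),
                   seed = config$seed, stages = list(), files = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(stages[[name]])) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seed = derive_seed(config$seed, name),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files[[file]] <<- unname(tools::md5sum(path))
    path
  }

  run_stage("simulate", function() {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, "simulate")
    ds <- generate_dataset(sim)
    state$expr <- ds$expr; state$meta <- ds$meta; state$truth <- ds$truth
    state$regions <- sim$regions
    write_matrix_tsv(ds$expr, file.path(config$out_dir, "expr.tsv"))
    manifest$files[["expr.tsv"]] <<-
      unname(tools::md5sum(file.path(config$out_dir, "expr.tsv")))
    emit(ds$meta, "meta.tsv")
    emit(data.frame(gene_id = names(ds$truth$per_gene_slope),
                    slope = unname(ds$truth$per_gene_slope),
                    is_gradient = names(ds$truth$per_gene_slope) %in%
                      ds$truth$gradient_gene_ids), "truth.tsv")
  })
  if (is.null(state$expr)) {
    state$expr <- config$expr; state$meta <- config$meta
    state$regions <- intersect(default_regions(), unique(state$meta$region))
    check_alignment(state$expr, state$meta)
  }

  run_stage("regress", function() {
    state$expr <- regress_covariates(state$expr, state$meta)
    write_matrix_tsv(state$expr, file.path(config$out_dir, "regressed.tsv"))
    manifest$files[["regressed.tsv"]] <<-
      unname(tools::md5sum(file.path(config$out_dir, "regressed.tsv")))
  })

  pairs <- region_pairs(state$regions)

  run_stage("pairwise_de", function() {
    rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      pk <- pair_key(pairs$region_a[i], pairs$region_b[i], state$regions)
      do.call(rbind, lapply(c("control", "case"), function(grp) {
        r <- count_de(state$expr, state$meta, pk, grp, alpha = config$alpha)
        data.frame(pair = pk$pair, group = grp, n_subjects = r$n_subjects,
                   n_de = r$n_de, stringsAsFactors = FALSE)
      }))
    }))
    state$de_summary <- rows
    emit(rows, "pairwise_de.tsv")
  })

  run_stage("ari_perm", function() {
    res <- ari_test_all(state$expr, state$meta, pairs, state$regions,
                        seed = derive_seed(config$seed, "ari_perm"),
                        B = config$B_perm, alpha = config$alpha)
    state$perm <- res
    emit(res$summary, "ari_permutation.tsv")
  })

  run_stage("ari_boot", function() {
    res <- bootstrap_ari(state$expr, state$meta, pairs, state$regions,
                         k = config$k, B = config$B_boot,
                         alpha = config$alpha,
                         seed = derive_seed(config$seed, "ari_boot"))
    state$boot <- res
    emit(res$summary, "ari_bootstrap.tsv")
  })

  run_stage("ari_genes", function() {
    if (is.null(state$perm)) stop("ari_genes requires the ari_perm stage")
    att <- state$perm$summary$pair[state$perm$summary$classification ==
                                     "attenuated"]
    if (!length(att)) {
      emit(data.frame(gene_id = character(0), pair = character(0),
                      occurrence_fraction = numeric(0),
                      assigned_region = character(0),
                      control_pair_p = numeric(0), group = character(0)),
           "ari_genes.tsv")
      return(invisible(NULL))
    }
    records <- do.call(rbind, lapply(att, function(pr) {
      i <- match(pr, pairs$pair)
      pk <- pair_key(pairs$region_a[i], pairs$region_b[i], state$regions)
      occ <- permutation_occurrence(
        state$expr, state$meta, pk, B = config$B_perm, alpha = config$alpha,
        seed = derive_seed(derive_seed(config$seed, "ari_perm"), pk$pair))
      ctrl_de <- count_de(state$expr, state$meta, pk, "control",
                          alpha = config$alpha)
      filter_ari_genes(ctrl_de, occ, state$expr, state$meta,
                       B = config$B_perm,
                       threshold = config$occurrence_threshold)
    }))
    cm <- control_region_medians(state$expr, state$meta, state$regions)
    groups <- build_ari_groups(records, cm, state$regions)
    records$group <- ifelse(records$gene_id %in% groups$ari_down, "ari_down",
                     ifelse(records$gene_id %in% groups$ari_up, "ari_up",
                            "unassigned"))
    state$ari_genes <- records; state$ari_groups <- groups
    emit(records, "ari_genes.tsv")
    writeLines(groups$ari_down, file.path(config$out_dir, "ari_down.txt"))
    writeLines(groups$ari_up, file.path(config$out_dir, "ari_up.txt"))
    manifest$files[["ari_down.txt"]] <<-
      unname(tools::md5sum(file.path(config$out_dir, "ari_down.txt")))
    manifest$files[["ari_up.txt"]] <<-
      unname(tools::md5sum(file.path(config$out_dir, "ari_up.txt")))
  })

  run_stage("slope", function() {
    region <- config$slope_region
    if (is.null(region)) region <- state$regions[length(state$regions)]
    fc_region <- compute_log2fc(state$expr, state$meta, region)
    fc_cortex <- compute_log2fc(state$expr, state$meta, "whole_cortex")
    fit <- slope_bootstrap(fc_region, fc_cortex,
                           seed = derive_seed(config$seed, "slope"))
    state$slope <- fit
    emit(data.frame(gene_id = names(fc_region), region_log2fc = fc_region,
                    cortex_log2fc = fc_cortex[names(fc_region)]),
         "effect_sizes.tsv")
    jsonlite::write_json(
      list(region = region, slope = fit$slope, intercept = fit$intercept,
           ci = fit$ci, p_vs_unity = fit$p_vs_unity, n_boot = fit$n_boot,
           n_genes = fit$n_genes, seed = fit$seed),
      file.path(config$out_dir, "slope_fit.json"), auto_unbox = TRUE,
      digits = NA)
    manifest$files[["slope_fit.json"]] <<-
      unname(tools::md5sum(file.path(config$out_dir, "slope_fit.json")))
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(state = state)))
}
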