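#' Occurrence of each gene among pseudo-control DE sets across permutations
#'
#' Re-runs the exact permutation stream of [ari_test()] (same subjects, same
#' seed, same tie and FDR rules) and counts, for each gene, in how many
#' permutations it was called differentially expressed in the pseudo-control
#' group. Genes whose DE status is insensitive to the diagnosis labelling
#' (occurrence near B) reflect labelling-independent regional differences and
#' are removed by the downstream filter.
#'
#' @param expr,meta,pair,B,alpha,seed,exact_limit,enumerate as in [ari_test()];
#'   pass the SAME seed (and enumerate flag) used for the permutation test,
#'   otherwise the streams differ and the occurrence counts are meaningless.
#' @return named integer vector (per gene) of occurrence counts in \[0, B\].
#' @export
permutation_occurrence <- function(expr, meta, pair, B = 10000, alpha = 0.05,
                                   seed = 1L, exact_limit = 25,
                                   enumerate = FALSE) {
  subj_case <- paired_subjects(meta, pair, "case")
  subj_ctrl <- paired_subjects(meta, pair, "control")
  d <- paired_diff_matrix(expr, meta, pair, c(subj_case, subj_ctrl))
  perms <- make_permutations(length(subj_case), length(subj_ctrl), B, seed,
                             enumerate)
  res <- de_count_columns(d, perms$control, alpha, exact_limit,
                          occurrence = TRUE)
  stats::setNames(as.integer(res$occurrence), rownames(expr))
}

#' Filter the true-control DE genes of an attenuated pair by occurrence
#'
#' Keeps a gene called DE between the pair's regions in the true control
#' subjects only if it appeared as pseudo-control DE in strictly less than
#' `threshold` of the permutations. Each retained gene is assigned to the
#' region where its control expression is higher (median across the paired
#' control subjects; mean as fallback on an exact median tie; a gene still
#' tied is excluded with a warning).
#'
#' @param true_control_de a `de_result` from [count_de()] on the control group.
#' @param occurrence named occurrence counts from [permutation_occurrence()]
#'   (same pair, shared permutation stream).
#' @param expr,meta the matrices the DE result was computed from.
#' @param B the permutation count behind `occurrence`.
#' @param threshold occurrence fraction cutoff, strict `<` (default 0.95).
#' @return data.frame (class keeps plain): gene_id, pair, occurrence_fraction,
#'   assigned_region, control_pair_p, one row per retained gene.
#' @export
filter_ari_genes <- function(true_control_de, occurrence, expr, meta,
                             B, threshold = 0.95) {
  pair <- true_control_de$pair
  tab <- true_control_de$table
  de_genes <- tab$gene_id[tab$de_flag]
  if (anyNA(occurrence[de_genes]))
    stop("occurrence is undefined for some true-control DE genes")
  keep <- de_genes[occurrence[de_genes] / B < threshold]
  if (!length(keep)) {
    return(data.frame(gene_id = character(0), pair = character(0),
                      occurrence_fraction = numeric(0),
                      assigned_region = character(0),
                      control_pair_p = numeric(0), stringsAsFactors = FALSE))
  }
  d <- paired_diff_matrix(expr, meta, pair, true_control_de$subjects)
  d <- d[keep, , drop = FALSE]
  med <- apply(d, 1, stats::median)   # > 0: higher in region_b
  tie <- med == 0
  med[tie] <- rowMeans(d[tie, , drop = FALSE])
  still_tied <- med == 0
  if (any(still_tied)) {
    warning("gene(s) with no expression difference excluded from assignment: ",
            paste(keep[still_tied], collapse = ", "))
  }
  keep2 <- keep[!still_tied]
  med <- med[!still_tied]
  data.frame(gene_id = keep2, pair = pair$pair,
             occurrence_fraction = unname(occurrence[keep2]) / B,
             assigned_region = ifelse(med > 0, pair$region_b, pair$region_a),
             control_pair_p = tab$p[match(keep2, tab$gene_id)],
             stringsAsFactors = FALSE)
}

#' Median control expression per region
#'
#' Per gene and region, the median across control subjects of the subject's
#' value in that region (each subject has at most one sample per region).
#'
#' @param expr genes x samples matrix; `meta` aligned metadata.
#' @param meta sample metadata.
#' @param regions regions to summarize (default: those present).
#' @return genes x regions matrix of control medians.
#' @export
control_region_medians <- function(expr, meta, regions = NULL) {
  m <- meta$diagnosis == "control"
  if (is.null(regions)) regions <- unique(meta$region[m])
  out <- sapply(regions, function(r) {
    cols <- which(m & meta$region == r)
    apply(expr[, cols, drop = FALSE], 1, stats::median)
  })
  rownames(out) <- rownames(expr)
  colnames(out) <- regions
  out
}

#' Build the union ARI gene groups along the anterior-posterior axis
#'
#' Takes the union (without duplicates) of the retained genes across all
#' attenuated source pairs and splits it into two groups by the direction of
#' the gene's control expression profile along the anterior-to-posterior axis:
#' `ari_down` if the Spearman correlation between its control median regional
#' expression and the region rank is positive (expression rises posteriorly —
#' by convention these posterior-high genes form the downregulated set),
#' `ari_up` if negative. Genes with zero correlation are left unassigned and
#' reported. A gene appearing with contradictory per-pair directions is
#' resolved by this all-region correlation, not its per-pair assignments.
#'
#' @param records data.frame rows from [filter_ari_genes()], possibly several
#'   pairs concatenated.
#' @param control_medians genes x regions matrix from
#'   [control_region_medians()].
#' @param regions ordered region vector (anterior first) defining ranks.
#' @return list with character vectors `ari_down`, `ari_up`, `unassigned`
#'   (disjoint; union = unique record genes).
#' @export
build_ari_groups <- function(records, control_medians,
                             regions = default_regions()) {
  if (!nrow(records)) stop("no retained ARI gene records")
  genes <- unique(records$gene_id)
  ranks <- seq_along(regions)
  present <- intersect(regions, colnames(control_medians))
  rho <- vapply(genes, function(g) {
    suppressWarnings(stats::cor(control_medians[g, present],
                                ranks[match(present, regions)],
                                method = "spearman"))
  }, 1.0)
  rho[is.na(rho)] <- 0
  out <- list(ari_down = sort(genes[rho > 0]),
              ari_up = sort(genes[rho < 0]),
              unassigned = sort(genes[rho == 0]))
  if (length(out$unassigned)) {
    message(length(out$unassigned),
            " gene(s) with flat regional profile left unassigned")
  }
  out
}
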