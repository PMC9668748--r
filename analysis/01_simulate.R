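#!/usr/bin/env Rscript
# Stage 1 — simulate the demo cohort.
#
# A multi-region case/control cohort with known ground truth: 20 subjects per
# group across the 11 default cortical regions, 10% region missingness, 5% of
# genes carrying an anterior-posterior gradient (slope SD 0.15 log2/rank
# step), gradients attenuated to 30% of their control strength in cases, plus
# a modest batch effect for the regression stage to remove. Counts are
# materialized so the QC stage can exercise the CPM/length filters.
#
# The gradient fraction and slope SD are kept small because this cohort goes
# through CPM: gradient genes grow convexly on the raw scale (2^x), so a toy
# cohort with many strongly graded genes shifts per-sample totals by region
# and library scaling leaks a compositional region signal into every flat
# gene — negligible at genome scale, dominant at a few hundred genes.

library(cortexARI)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(
  n_control = 20, n_case = 20, n_genes = 2000,
  gradient_fraction = 0.05, gradient_effect_sd = 0.15, noise_sd = 0.3,
  missing_rate = 0.1, attenuation = 0.3,
  covariate_effects = list(batch = 0.3),
  emit_counts = TRUE, nb_dispersion = 20, seed = 20L)

ds <- generate_dataset(cfg)
cm <- emit_counts(ds$expr, cfg, lib_size = 2e6)

write_matrix_tsv(cm$counts, file.path(out, "counts.tsv"))
write_meta_tsv(ds$meta, file.path(out, "meta.tsv"))
write.table(data.frame(gene_id = names(ds$truth$per_gene_slope),
                       slope = unname(ds$truth$per_gene_slope),
                       is_gradient = names(ds$truth$per_gene_slope) %in%
                         ds$truth$gradient_gene_ids),
            file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(cm$effective_length),
                       effective_length = unname(cm$effective_length)),
            file.path(out, "effective_lengths.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d samples (%d subjects, %d regions)\n",
            nrow(cm$counts), ncol(cm$counts),
            length(unique(ds$meta$subject_id)),
            length(unique(ds$meta$region))))
cat(sprintf("%d gradient genes planted; attenuation lambda = %.2f\n",
            length(ds$truth$gradient_gene_ids), cfg$attenuation))
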