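#!/usr/bin/env Rscript
# Stage 2 — QC and covariate regression.
#
# CPM/length feature filtering, log2(CPM + 0.5) normalization, PC +
# connectivity sample outlier removal (batch x lobe groups), then per-gene
# mixed-model regression that removes batch, sex and age effects while keeping
# subject, diagnosis and region — the regressed matrix every regional-identity
# statistic consumes.

library(cortexARI)

counts <- read_matrix_tsv("results/data/counts.tsv")
meta <- read_meta_tsv("results/data/meta.tsv")
lens <- read.delim("results/data/effective_lengths.tsv")
cm <- count_matrix(counts, setNames(lens$effective_length, lens$gene_id))

cm <- filter_features(cm)            # CPM > 0.1 in >= 30% of samples, >= 15 bp
cat(sprintf("feature filter: %d genes retained\n", nrow(cm$counts)))

expr <- log_normalize(cm)

qc <- detect_outliers(expr, meta)
cat(sprintf("outliers flagged: %d of %d samples\n", sum(qc$outlier), nrow(qc)))
keep <- !qc$outlier
expr <- expr[, keep, drop = FALSE]
meta <- meta[keep, ]

reg <- regress_covariates(expr, meta, nuisance = c("batch", "sex", "age"))
cat(sprintf("regressed out: %s (%d genes fell back to OLS)\n",
            paste(attr(reg, "removed_covariates"), collapse = ", "),
            length(attr(reg, "fallback_genes"))))

write_matrix_tsv(reg, "results/regressed.tsv")
write_meta_tsv(meta, "results/meta_qc.tsv")
write.table(qc, "results/outlier_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
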