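#!/usr/bin/env Rscript
# Stage 3 — paired regional differential expression.
#
# For each of the 55 region pairs and each diagnosis group: paired Wilcoxon
# signed-rank test per gene across subjects with both regions, BH FDR across
# genes, DE counted at q < 0.05. The per-pair count difference (case minus
# control) is the raw material of the attenuation tests.

library(cortexARI)

expr <- read_matrix_tsv("results/regressed.tsv")
meta <- read_meta_tsv("results/meta_qc.tsv")
pairs <- region_pairs()

rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  pk <- pair_key(pairs$region_a[i], pairs$region_b[i])
  do.call(rbind, lapply(c("control", "case"), function(grp) {
    r <- count_de(expr, meta, pk, grp)
    data.frame(pair = pk$pair, group = grp, n_subjects = r$n_subjects,
               n_de = r$n_de)
  }))
}))
write.table(rows, "results/pairwise_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

wide <- reshape(rows, idvar = "pair", timevar = "group", direction = "wide")
wide$diff <- wide$n_de.case - wide$n_de.control
cat(sprintf("%d of %d pairs show fewer DE genes in cases\n",
            sum(wide$diff < 0), nrow(wide)))
cat("largest reductions:\n")
print(head(wide[order(wide$diff), c("pair", "n_de.control", "n_de.case", "diff")], 5),
      row.names = FALSE)
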