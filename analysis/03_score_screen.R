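#!/usr/bin/env Rscript
# Score the simulated screen: median-of-ratios normalization, per-guide
# log2 fold change (T14 vs T0, replicates averaged on the normalized
# scale), within-line z-scores, and gene-level gene scores (median LFC) and
# CRISPR viability scores (median z). Depletion cutoffs: -1 for the normal
# and first two cancer lines, -0.5 for the third (lower-efficacy role).

library(crisprselect)

manifest <- read_manifest("results/screen/manifest.tsv")
sheet <- sample_sheet(read.csv("results/screen/sample_sheet.csv"))
cm <- read_count_table("results/screen/counts.tsv", sheet, manifest = manifest)

cutoffs <- c(normal = -1, cancer_1 = -1, cancer_2 = -1, cancer_3 = -0.5)
scores <- score_screen(cm, cutoffs = cutoffs)

write.table(scores$guide_lfc, "results/guide_lfc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scores$gene_scores, "results/gene_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("normalization: %s; size factors %.3f-%.3f\n",
            scores$normalization$method,
            min(scores$normalization$size_factors),
            max(scores$normalization$size_factors)))
g <- scores$gene_scores
for (cl in unique(g$cell_line)) {
  sel <- g[g$cell_line == cl & !g$is_control, ]
  cat(sprintf("%s: %d genes scored, %d below the %.1f cutoff\n",
              cl, nrow(sel), sum(sel$gene_score <= cutoffs[[cl]]),
              cutoffs[[cl]]))
}
cat("wrote results/guide_lfc.tsv and results/gene_scores.tsv\n")
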