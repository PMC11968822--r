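#!/usr/bin/env Rscript
# Screen quality control: per-sample representation (Gini index, zero
# fraction, coverage), essential-guide depletion tests, and per-line
# ROC-AUC separating planted core-essential from neutral genes by gene
# score — the screen-performance readout.

library(crisprselect)

truth <- read.delim("results/screen/truth.tsv")
lfcs <- read.delim("results/guide_lfc.tsv")
class(lfcs) <- c("guide_lfc", "data.frame")
scores <- read.delim("results/gene_scores.tsv")
class(scores) <- c("gene_scores", "data.frame")
manifest <- read_manifest("results/screen/manifest.tsv")
sheet <- sample_sheet(read.csv("results/screen/sample_sheet.csv"))
cm <- read_count_table("results/screen/counts.tsv", sheet, manifest = manifest)

sets <- reference_gene_sets(truth$gene[truth$class == "core_essential"],
                            truth$gene[truth$class == "neutral"])

qc <- qc_report(cm, lfcs = lfcs, gene_sets = sets)
write_qc_report(qc, "results/qc")

cat(sprintf("Gini index range across samples: %.3f-%.3f\n",
            min(qc$samples$gini), max(qc$samples$gini)))
cat("essential-guide depletion (rank-sum, essential < controls):\n")
print(qc$depletion, row.names = FALSE)

for (cl in unique(scores$cell_line)) {
  roc <- roc_auc(scores[scores$cell_line == cl, ], sets)
  write_roc_points(roc, file.path("results/qc",
                                  paste0("roc_", cl, ".tsv")))
  cat(sprintf("%s: essential-vs-neutral AUC = %.3f\n", cl, roc$auc))
}
cat("wrote results/qc/\n")
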