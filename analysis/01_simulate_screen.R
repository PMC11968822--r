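#!/usr/bin/env Rscript
# Simulate the comparative dropout screen that the rest of the workflow
# analyzes: 1,000 genes x 4 guides + 50 non-targeting controls, one
# nonmalignant + three cancer lines, T0 vs T14 in triplicate, 500x depth,
# 14 population doublings. Writes the plain-text inputs a real screen would
# provide (manifest, counts, sample sheet) plus the ground truth used later
# for recovery assessment.

library(crisprselect)

cfg <- sim_config(seed = 1)
sim <- simulate_screen(cfg)

dir.create("results/screen", recursive = TRUE, showWarnings = FALSE)
write_sim_screen(sim, "results/screen")

rep <- validate_manifest(sim$manifest)
cat(sprintf("library: %d guides = %d targeting + %d controls over %d genes\n",
            rep$n_total, rep$n_targeting, rep$n_controls, rep$n_genes))
cat(sprintf("samples: %d (%s)\n", nrow(sim$counts$samples),
            paste(unique(sim$counts$samples$cell_line), collapse = ", ")))
print(table(truth_class = sim$truth$genes$class))
cat("wrote results/screen/{manifest,counts,truth}.tsv + sample_sheet.csv\n")
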