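#!/usr/bin/env Rscript
# Demonstrate the read-level entry point on a down-scaled screen: emit
# FASTQ files (staggered prefixes + vector barcode + spacer) realizing two
# simulated samples, quantify them by exact spacer matching, and confirm
# the counts reproduce the generating column exactly.

library(crisprselect)

cfg <- sim_config(n_genes = 100, guides_per_gene = 4, n_controls = 10,
                  coverage = 100, seed = 1)
sim <- simulate_screen(cfg)

dir.create("results/fastq_demo", recursive = TRUE, showWarnings = FALSE)
take <- sim$counts$samples$sample_id[1:2]
paths <- vapply(take, function(sid) {
  p <- file.path("results/fastq_demo", paste0(sid, ".fastq.gz"))
  simulate_fastq(sim$counts$counts[, sid], sim$manifest, p, seed = 1)
  p
}, character(1))

cm <- count_guides(paths, sim$manifest, sim$counts$samples[1:2, ])
stopifnot(identical(cm$counts[, take], sim$counts$counts[, take]))
write_count_table(cm, "results/fastq_demo/counts_from_fastq.tsv")

cat(sprintf("emitted and re-counted %s reads across %d samples\n",
            format(sum(cm$totals$total_reads), big.mark = ","),
            length(take)))
cat("round trip exact: recovered counts identical to the generating column\n")
cat(sprintf("unmatched reads: %d\n", sum(cm$totals$unmatched_reads)))
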