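Package: crisprselect
Title: Comparative Pooled CRISPR Knockout Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for comparative pooled CRISPR knockout
    screens across multiple cell lines: guide library handling, spacer
    extraction and guide quantification from screen FASTQ reads, read-count
    normalization, per-guide log2 fold changes and within-screen z-scores,
    median-based gene scores and CRISPR viability scores, screen quality
    control (Gini index of library representation, essential-gene depletion
    tests, ROC-AUC against reference essential/nonessential gene sets), and
    a cutoff-based comparative filter that separates cancer-selective
    dependencies from common essentials. Includes a negative-binomial
    generative model of a dropout screen (fitness effects over population
    doublings, variable guide efficacy, representation skew) with known
    truth labels for end-to-end recovery testing, plus small closed-form
    helpers for library-coverage arithmetic, immunoreactivity scores, and
    competitive-proliferation time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
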