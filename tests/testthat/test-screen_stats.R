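test_that("median-ratio size factors match their definition and DESeq2", {
  m <- toy_manifest(n_genes = 2, guides_per_gene = 2, n_controls = 0)
  sheet <- toy_sheet(replicates = 1)

  # two identical samples: factors 1, values = counts
  mat <- matrix(c(10L, 20L, 30L, 40L, 10L, 20L, 30L, 40L), nrow = 4)
  norm <- normalize_counts(toy_counts(mat, m, sheet), "median_ratio")
  expect_equal(unname(norm$size_factors), c(1, 1))
  expect_equal(unname(norm$values), mat * 1.0, ignore_attr = TRUE)

  # 4-guide toy matrix against a hand-evaluated median-of-ratios oracle
  mat2 <- matrix(c(100L, 50L, 400L, 10L, 200L, 100L, 100L, 40L), nrow = 4)
  cm2 <- toy_counts(mat2, m, sheet)
  geo <- apply(mat2, 1, function(r) exp(mean(log(r))))
  oracle_sf <- apply(mat2, 2, function(col) median(col / geo))
  norm2 <- normalize_counts(cm2, "median_ratio")
  expect_equal(unname(norm2$size_factors), oracle_sf, tolerance = 1e-12)
  expect_equal(unname(norm2$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat2)),
               tolerance = 1e-9)
})

test_that("total-count factors scale samples to the mean depth", {
  m <- toy_manifest(n_genes = 2, guides_per_gene = 2, n_controls = 0)
  sheet <- toy_sheet(replicates = 1)
  mat <- matrix(c(rep(250000L, 4), rep(500000L, 4)), nrow = 4)
  norm <- normalize_counts(toy_counts(mat, m, sheet), "total_count")
  expect_equal(unname(norm$size_factors[2] / norm$size_factors[1]), 2)
  expect_equal(unname(colSums(norm$values)), rep(1.5e6, 2))
})

test_that("median-ratio is refused when undefined, advising total_count", {
  m <- toy_manifest(n_genes = 2, guides_per_gene = 2, n_controls = 0)
  one <- toy_sheet()[1, , drop = FALSE]
  mat1 <- matrix(1:4, ncol = 1)
  expect_error(normalize_counts(toy_counts(mat1, m, one), "median_ratio"),
               "total_count")
  # every guide has a zero somewhere
  sheet <- toy_sheet(replicates = 1)
  mat0 <- matrix(c(0L, 1L, 2L, 0L, 3L, 0L, 0L, 4L), nrow = 4)
  expect_error(normalize_counts(toy_counts(mat0, m, sheet), "median_ratio"),
               "total_count")
  # auto falls back instead
  expect_message(normalize_counts(toy_counts(mat0, m, sheet), "auto"),
                 "total_count")
  norm <- suppressMessages(normalize_counts(toy_counts(mat0, m, sheet),
                                            "auto"))
  expect_equal(norm$method, "total_count")
})

test_that("guide LFC follows log2((T14 + pc) / (T0 + pc))", {
  m <- toy_manifest(n_genes = 1, guides_per_gene = 3, n_controls = 0)
  sheet <- toy_sheet(replicates = 1)
  # equal sample totals so total_count leaves values untouched
  mat <- matrix(c(100L, 1023L, 77L, 25L, 0L, 1175L), nrow = 3)
  norm <- normalize_counts(toy_counts(mat, m, sheet), "total_count")
  l <- guide_lfc(norm, "L1", pseudocount = 1)
  expect_equal(l$lfc[1], log2(26 / 101))
  expect_equal(l$lfc[2], -10)

  # T0 == T14 everywhere gives identically zero LFC
  matid <- matrix(rep(c(5L, 50L, 500L), 2), nrow = 3)
  l0 <- guide_lfc(normalize_counts(toy_counts(matid, m, sheet),
                                   "total_count"), "L1")
  expect_equal(l0$lfc, rep(0, 3))

  expect_error(guide_lfc(norm, "missing_line"), "missing_line")
})

test_that("replicate modes agree when replicates are identical", {
  m <- toy_manifest(n_genes = 2, guides_per_gene = 2, n_controls = 0)
  sheet <- toy_sheet(replicates = 2)
  base <- c(40L, 80L, 120L, 160L)
  mat <- cbind(base, base, base %/% 2L, base %/% 2L)
  norm <- normalize_counts(toy_counts(mat, m, sheet), "total_count")
  a <- guide_lfc(norm, "L1", replicate_mode = "mean_counts")
  b <- guide_lfc(norm, "L1", replicate_mode = "mean_lfc")
  expect_equal(a$lfc, b$lfc, tolerance = 1e-12)
})

test_that("z-scores follow the (x - mean) / sd contract", {
  d <- lfc_frame(c(-2, 0, 2), gene = "G")
  z <- zscore_lfc(d)
  expect_equal(z$zscore, c(-1, 0, 1))  # sample sd = 2

  set.seed(11)
  d2 <- lfc_frame(rnorm(1000, -0.5, 1.7), gene = "G")
  z2 <- zscore_lfc(d2)
  # two-pass oracle
  mu <- sum(d2$lfc) / 1000
  s <- sqrt(sum((d2$lfc - mu)^2) / 999)
  expect_equal(z2$zscore, (d2$lfc - mu) / s, tolerance = 1e-12)
  expect_lt(abs(mean(z2$zscore)), 1e-9)
  expect_lt(abs(sd(z2$zscore) - 1), 1e-9)

  expect_error(zscore_lfc(lfc_frame(c(1, 1, 1), gene = "G")), "sd = 0")
  expect_error(zscore_lfc(lfc_frame(1, gene = "G")), ">= 2")
})

test_that("gene scores are medians with the midpoint convention", {
  cuts <- c(L1 = -1)
  d <- lfc_frame(c(-3, -1, -2, -4, -2), gene = c(rep("A", 3), rep("B", 2)))
  d <- zscore_lfc(d)
  g <- gene_scores(d, cuts)
  expect_equal(g$gene_score[g$gene == "A"], -2)   # odd-count median
  expect_equal(g$gene_score[g$gene == "B"], -3)   # even: midpoint mean
  expect_equal(g$n_scoring_guides[g$gene == "A"], 3L)
  expect_true(all(g$n_scoring_guides <= g$n_guides))

  # random guide sets against a sort-and-pick oracle
  sort_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(2:9, 1))
    di <- zscore_lfc(lfc_frame(c(x, 0, 1), gene = c(rep("G", length(x)),
                                                    "pad1", "pad2")))
    gi <- gene_scores(di, cuts)
    expect_equal(gi$gene_score[gi$gene == "G"], sort_median(x))
  }
})

test_that("gene and viability scores are permutation-invariant", {
  set.seed(21)
  d <- lfc_frame(rnorm(40), gene = sample(sprintf("G%d", 1:10), 40, TRUE))
  d <- zscore_lfc(d)
  g1 <- gene_scores(d, c(L1 = -1))
  perm <- d[sample(nrow(d)), ]
  g2 <- gene_scores(perm, c(L1 = -1))
  expect_equal(g2, g1, ignore_attr = TRUE)
})

test_that("lowering one guide LFC never raises its gene score", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(6)
    j <- sample(6, 1)
    y <- x; y[j] <- y[j] - runif(1, 0, 3)
    med <- function(v) median(v)
    expect_lte(med(y), med(x))
  }
})

test_that("controls aggregate under the control pseudo-gene", {
  m <- toy_manifest(n_genes = 2, guides_per_gene = 2, n_controls = 3)
  sheet <- toy_sheet(replicates = 1)
  set.seed(3)
  mat <- matrix(rpois(14, 100), nrow = 7)
  sc <- score_screen(toy_counts(mat, m, sheet), cutoffs = c(L1 = -1))
  g <- sc$gene_scores
  expect_true("NO_TARGET" %in% g$gene)
  expect_true(g$is_control[g$gene == "NO_TARGET"])
  expect_equal(g$n_guides[g$gene == "NO_TARGET"], 3L)
  # z-scoring spans ALL guides of the line, controls included
  expect_lt(abs(mean(sc$guide_lfc$zscore)), 1e-9)
})

test_that("total-count LFC at pseudocount 0 ignores per-sample scaling", {
  m <- toy_manifest(n_genes = 2, guides_per_gene = 2, n_controls = 0)
  sheet <- toy_sheet(replicates = 1)
  mat <- matrix(c(10L, 20L, 30L, 40L, 8L, 25L, 31L, 36L), nrow = 4)
  l1 <- guide_lfc(normalize_counts(toy_counts(mat, m, sheet), "total_count"),
                  "L1", pseudocount = 0)
  mat2 <- mat; mat2[, 2] <- mat2[, 2] * 7L
  l2 <- guide_lfc(normalize_counts(toy_counts(mat2, m, sheet), "total_count"),
                  "L1", pseudocount = 0)
  expect_equal(l2$lfc, l1$lfc, tolerance = 1e-12)
})

test_that("under a null screen, viability scores center at zero", {
  cfg <- sim_config(n_genes = 300, guides_per_gene = 4, n_controls = 30,
                    effect_sizes = c(core_essential = 0,
                                     cancer_selective = 0, enriched = 0),
                    seed = 19)
  sim <- simulate_screen(cfg)
  sc <- score_screen(sim$counts, cutoffs = default_cutoffs)
  g <- sc$gene_scores
  for (cl in cfg$cell_lines) {
    v <- g$viability_score[g$cell_line == cl & !g$is_control]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(median(v)), 3 * max(se, 1e-3))
    ctrl_v <- g$viability_score[g$cell_line == cl & g$is_control]
    expect_lt(abs(ctrl_v), 0.5)
  }
})
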