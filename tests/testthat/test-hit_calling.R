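# gene_scores-shaped table for one or more genes across the 4 default lines
mk_scores <- function(gene, gs, vs, nsg, is_control = FALSE,
                      lines = c("normal", "cancer_1", "cancer_2", "cancer_3")) {
  d <- data.frame(gene = rep(gene, each = length(lines)),
                  cell_line = rep(lines, length(gene)),
                  gene_score = as.vector(t(gs)),
                  viability_score = as.vector(t(vs)),
                  n_guides = 4L,
                  n_scoring_guides = as.integer(as.vector(t(nsg))),
                  is_control = rep(is_control, each = length(lines)),
                  stringsAsFactors = FALSE)
  class(d) <- c("gene_scores", "data.frame")
  d
}

test_that("hit_config validates lines and cutoffs", {
  expect_error(hit_config("A", c("A", "B"), c(A = -1, B = -1)), "normal_line")
  expect_error(hit_config("N", "C", c(N = -1)), "missing")
  expect_error(hit_config("N", "C", c(N = -1, C = 0.5)), "negative")
  expect_error(default_hit_config(min_scoring_guides = 0), ">= 1")
})

test_that("the comparative filter applies the published rule set", {
  cfg <- default_hit_config()

  # depleted past cutoff in all cancer lines, enough guides, flexible normal
  sel <- mk_scores("HIT",
                   gs = rbind(c(-0.1, -2.0, -1.6, -0.8)),
                   vs = rbind(c(-0.1, -2.2, -1.9, -1.0)),
                   nsg = rbind(c(0, 3, 3, 3)))
  expect_equal(call_hits(sel, cfg)$call, "cancer_selective")

  # normal line more depleted than every cancer line: not selective
  com <- mk_scores("HIT",
                   gs = rbind(c(-2.5, -2.0, -1.6, -0.8)),
                   vs = rbind(c(-3.0, -2.2, -1.9, -1.0)),
                   nsg = rbind(c(3, 3, 3, 3)))
  expect_equal(call_hits(com, cfg)$call, "common_depleted")

  # one cancer line supported by a single scoring guide: no call
  weak <- mk_scores("HIT",
                    gs = rbind(c(-0.1, -2.0, -1.6, -0.8)),
                    vs = rbind(c(-0.1, -2.2, -1.9, -1.0)),
                    nsg = rbind(c(0, 3, 1, 3)))
  expect_equal(call_hits(weak, cfg)$call, "none")

  # gene score above the mirrored positive cutoff everywhere: enriched
  enr <- mk_scores("UP",
                   gs = rbind(c(0.2, 1.4, 2.0, 0.6)),
                   vs = rbind(c(0.2, 1.5, 2.2, 0.9)),
                   nsg = rbind(c(0, 0, 0, 0)))
  expect_equal(call_hits(enr, cfg)$call, "enriched")

  # controls are never called even when their numbers would qualify
  ctrl <- mk_scores("NO_TARGET",
                    gs = rbind(c(-0.1, -2.0, -1.6, -0.8)),
                    vs = rbind(c(-0.1, -2.2, -1.9, -1.0)),
                    nsg = rbind(c(0, 3, 3, 3)), is_control = TRUE)
  expect_equal(call_hits(ctrl, cfg)$call, "none")

  # a configured line missing entirely is an error
  expect_error(call_hits(sel[sel$cell_line != "cancer_2", ], cfg),
               "cancer_2")
})

test_that("a lower-efficacy line is judged against its milder cutoff", {
  cfg <- default_hit_config()
  # -0.8 passes cancer_3's -0.5 cutoff but would fail a -1 cutoff
  ok <- mk_scores("HIT",
                  gs = rbind(c(0, -1.2, -1.1, -0.8)),
                  vs = rbind(c(0, -2, -2, -1)),
                  nsg = rbind(c(0, 2, 2, 2)))
  expect_equal(call_hits(ok, cfg)$call, "cancer_selective")
  # -0.4 fails even the milder cutoff
  bad <- mk_scores("HIT",
                   gs = rbind(c(0, -1.2, -1.1, -0.4)),
                   vs = rbind(c(0, -2, -2, -0.5)),
                   nsg = rbind(c(0, 2, 2, 2)))
  expect_equal(call_hits(bad, cfg)$call, "none")
})

test_that("guide-level normal constraint demands per-guide selectivity", {
  cfg <- default_hit_config(normal_constraint = "guide_level")
  gs <- mk_scores("HIT",
                  gs = rbind(c(-0.1, -2.0, -1.6, -0.8)),
                  vs = rbind(c(-0.1, -2.2, -1.9, -1.0)),
                  nsg = rbind(c(0, 2, 2, 2)))
  mk_lfcs <- function(normal_lfc) {
    rbind(
      lfc_frame(normal_lfc, gene = "HIT", cell_line = "normal",
                guide_id = c("h1", "h2"), zscore = 0),
      lfc_frame(c(-2, -2), gene = "HIT", cell_line = "cancer_1",
                guide_id = c("h1", "h2"), zscore = 0),
      lfc_frame(c(-1.6, -1.7), gene = "HIT", cell_line = "cancer_2",
                guide_id = c("h1", "h2"), zscore = 0),
      lfc_frame(c(-0.8, -0.9), gene = "HIT", cell_line = "cancer_3",
                guide_id = c("h1", "h2"), zscore = 0)
    )
  }
  # every scoring guide is milder in the normal line: selective
  h <- call_hits(gs, cfg, lfcs = mk_lfcs(c(-0.1, -0.2)))
  expect_equal(h$call, "cancer_selective")
  # one guide as depleted in normal as in a cancer line: constraint fails
  h2 <- call_hits(gs, cfg, lfcs = mk_lfcs(c(-2.0, -0.2)))
  expect_equal(h2$call, "none")
})

test_that("selective calls behave monotonically", {
  cfg <- default_hit_config()
  base <- mk_scores("HIT",
                    gs = rbind(c(-0.1, -2.0, -1.6, -0.8)),
                    vs = rbind(c(-0.1, -2.2, -1.9, -1.0)),
                    nsg = rbind(c(0, 3, 3, 3)))
  expect_equal(call_hits(base, cfg)$call, "cancer_selective")
  # deepening a cancer line keeps the call
  deeper <- base
  i <- deeper$cell_line == "cancer_1"
  deeper$gene_score[i] <- -4
  deeper$viability_score[i] <- -4
  expect_equal(call_hits(deeper, cfg)$call, "cancer_selective")
  # deepening the normal line moves the call toward common/none
  worse_normal <- base
  j <- worse_normal$cell_line == "normal"
  worse_normal$gene_score[j] <- -3
  worse_normal$viability_score[j] <- -3
  worse_normal$n_scoring_guides[j] <- 3L
  expect_true(call_hits(worse_normal, cfg)$call %in%
                c("common_depleted", "none"))
})

test_that("pooled guide-support mode relaxes the per-line rule", {
  strict <- default_hit_config()
  pooled <- default_hit_config(scoring_guides_scope = "pooled")
  one_each <- mk_scores("HIT",
                        gs = rbind(c(-0.1, -2.0, -1.6, -0.8)),
                        vs = rbind(c(-0.1, -2.2, -1.9, -1.0)),
                        nsg = rbind(c(0, 1, 1, 1)))
  expect_equal(call_hits(one_each, strict)$call, "none")
  expect_equal(call_hits(one_each, pooled)$call, "cancer_selective")
})

test_that("rank_genes sorts stably with documented tie-breaks", {
  g <- mk_scores(c("A", "B", "C"),
                 gs = rbind(c(0, -3, -3, -3), c(0, -1, -1, -1),
                            c(0, 2, 2, 2)),
                 vs = rbind(c(0, -3, -3, -3), c(0, -1, -1, -1),
                            c(0, 2, 2, 2)),
                 nsg = matrix(2, 3, 4))
  r <- rank_genes(g, line = "cancer_1", k = 1)
  expect_equal(r$top_depleted$gene, "A")
  expect_equal(r$top_enriched$gene, "C")

  # ties break by gene symbol
  tie <- mk_scores(c("B", "A"),
                   gs = rbind(c(0, -1, -1, -1), c(0, -1, -1, -1)),
                   vs = rbind(c(0, -1, -1, -1), c(0, -1, -1, -1)),
                   nsg = matrix(2, 2, 4))
  rt <- rank_genes(tie, line = "cancer_1", k = 2)
  expect_equal(rt$ranked$gene, c("A", "B"))

  # k beyond the table returns everything
  rk <- rank_genes(g, line = "cancer_1", k = 99)
  expect_equal(nrow(rk$top_depleted), 3L)

  # aggregate ranking equals a full-sort oracle on mean viability
  set.seed(23)
  n <- 100
  vs <- matrix(rnorm(n * 4), n, 4)
  gg <- mk_scores(sprintf("G%03d", 1:n), gs = vs, vs = vs,
                  nsg = matrix(2, n, 4))
  ra <- rank_genes(gg, cancer_lines = c("cancer_1", "cancer_2", "cancer_3"))
  oracle <- sprintf("G%03d", order(rowMeans(vs[, 2:4])))
  expect_equal(ra$ranked$gene, oracle)
})
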