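#' Gini index of guide representation
#'
#' Inequality of per-guide read counts within one sample; 0 means perfectly
#' even library representation, values near 1 mean a few guides hold nearly
#' all reads. Computed on the ascending-sorted counts x as
#' `G = sum((2i - n - 1) * x_i) / (n * sum(x))`, which equals the mean
#' absolute pairwise difference divided by twice the mean. Zero-count guides
#' are part of the representation and included by default.
#'
#' @param x Non-negative counts for one sample (length >= 2, not all zero).
#' @param include_zeros Keep zero-count guides (default) or drop them first.
#' @return Gini index in `[0, 1)`.
#' @export
gini_index <- function(x, include_zeros = TRUE) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative and non-NA")
  if (!include_zeros) x <- x[x > 0]
  if (length(x) < 2L) stop("need >= 2 guides")
  if (all(x == 0)) stop("all counts are zero; Gini undefined")
  n <- length(x)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * sum(xs))
}

#' Depletion test of reference essential genes
#'
#' One-sided Wilcoxon rank-sum test comparing LFCs of guides targeting
#' reference essential genes against non-targeting control guides
#' (alternative: essential lower). A working dropout screen shows a strongly
#' negative shift of the essential-guide distribution while controls stay
#' centered.
#'
#' @param lfcs A `guide_lfc` data.frame for a single cell line.
#' @param gene_sets A [reference_gene_sets()].
#' @param min_group Minimum guides required in each group.
#' @return List: `statistic` (rank-sum W), `p_value`, `median_essential`,
#'   `median_control`, `n_essential`, `n_control`.
#' @export
essential_depletion_test <- function(lfcs, gene_sets, min_group = 10L) {
  stopifnot(inherits(gene_sets, "reference_gene_sets"))
  if (length(unique(lfcs$cell_line)) != 1L) {
    stop("run the depletion test one cell line at a time")
  }
  ess <- lfcs$lfc[lfcs$gene %in% gene_sets$essential & !lfcs$is_control]
  ctrl <- lfcs$lfc[lfcs$is_control]
  if (length(ess) < min_group || length(ctrl) < min_group) {
    stop(sprintf("too few guides (essential %d, control %d; need >= %d each)",
                 length(ess), length(ctrl), min_group))
  }
  wt <- stats::wilcox.test(ess, ctrl, alternative = "less", exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_essential = stats::median(ess),
       median_control = stats::median(ctrl),
       n_essential = length(ess), n_control = length(ctrl))
}

#' ROC curve separating essential from nonessential genes
#'
#' Screen-performance metric: reference essential genes are the positives,
#' nonessential genes the negatives, and a gene is called positive when its
#' depletion score is at or below a threshold (more depleted = more
#' positive). Thresholds sweep all observed scores, ties sharing a
#' threshold, and the AUC is the trapezoidal area — equal to the
#' Mann-Whitney c-statistic with ties counted 1/2.
#'
#' @param scores A `gene_scores` data.frame for a single cell line.
#' @param gene_sets A [reference_gene_sets()].
#' @param score_col Score to rank by: the gene score (median LFC, default)
#'   or the viability score (median z).
#' @return Object of class `roc_curve`: `thresholds` (sweep order, starting
#'   below all scores), `fpr`, `tpr` (nondecreasing, from (0,0) to (1,1)),
#'   `auc`, `n_pos`, `n_neg`, and `excluded` (reference genes absent from
#'   the score table).
#' @export
roc_auc <- function(scores, gene_sets,
                    score_col = c("gene_score", "viability_score")) {
  stopifnot(inherits(gene_sets, "reference_gene_sets"))
  score_col <- match.arg(score_col)
  if (length(unique(scores$cell_line)) > 1L) {
    stop("ROC is computed one cell line at a time")
  }
  s <- stats::setNames(scores[[score_col]], scores$gene)
  pos <- intersect(gene_sets$essential, names(s))
  neg <- intersect(gene_sets$nonessential, names(s))
  excluded <- setdiff(c(gene_sets$essential, gene_sets$nonessential), names(s))
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need >= 2 essential and >= 2 nonessential genes with scores")
  }
  sp <- unname(s[pos])
  sn <- unname(s[neg])
  th <- sort(unique(c(sp, sn)))
  tpr <- vapply(th, function(t) mean(sp <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(sn <= t), numeric(1))
  fpr <- c(0, fpr)
  tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(
    list(thresholds = c(-Inf, th), fpr = fpr, tpr = tpr, auc = auc,
         n_pos = length(pos), n_neg = length(neg), excluded = excluded),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Per-sample screen quality report
#'
#' Raw-count quality summaries for each sample: read tallies, fraction of
#' zero-count guides, coverage (matched reads per library guide), count
#' percentiles, and the Gini index of representation. When guide LFCs and
#' reference sets are supplied, a per-line essential-depletion test is added.
#'
#' @param cm A [count_matrix()].
#' @param lfcs Optional `guide_lfc` data.frame covering one or more lines.
#' @param gene_sets Optional [reference_gene_sets()] (needed with `lfcs`).
#' @return List of class `qc_report`: `samples` data.frame and, when
#'   available, `depletion` (per cell line statistic/p-value).
#' @export
qc_report <- function(cm, lfcs = NULL, gene_sets = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  n_guides <- nrow(cm$counts)
  per_sample <- lapply(seq_len(ncol(cm$counts)), function(j) {
    x <- cm$counts[, j]
    q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
    data.frame(
      sample_id = colnames(cm$counts)[j],
      total_reads = cm$totals$total_reads[j],
      matched_reads = cm$totals$matched_reads[j],
      zero_fraction = mean(x == 0),
      coverage = cm$totals$matched_reads[j] / n_guides,
      p10 = q[1], p50 = q[2], p90 = q[3],
      gini = gini_index(x),
      stringsAsFactors = FALSE
    )
  })
  out <- list(samples = do.call(rbind, c(per_sample,
                                         list(make.row.names = FALSE))))
  if (!is.null(lfcs) && !is.null(gene_sets)) {
    lines <- unique(lfcs$cell_line)
    dep <- lapply(lines, function(cl) {
      t <- essential_depletion_test(lfcs[lfcs$cell_line == cl, , drop = FALSE],
                                    gene_sets)
      data.frame(cell_line = cl, statistic = t$statistic,
                 p_value = t$p_value, median_essential = t$median_essential,
                 median_control = t$median_control, stringsAsFactors = FALSE)
    })
    out$depletion <- do.call(rbind, c(dep, list(make.row.names = FALSE)))
  }
  class(out) <- "qc_report"
  out
}

#' Write a QC report to disk
#'
#' Emits `qc_samples.tsv` (and `qc_depletion.tsv` when present) plus a
#' combined `qc_report.json` under `dir`.
#'
#' @param report A [qc_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$samples, file.path(dir, "qc_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$depletion)) {
    write.table(report$depletion, file.path(dir, "qc_depletion.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(report), file.path(dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write ROC curve points to TSV
#'
#' @param roc A `roc_curve` from [roc_auc()].
#' @param path Output TSV (`threshold`, `fpr`, `tpr` columns).
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  write.table(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                         tpr = roc$tpr),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
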