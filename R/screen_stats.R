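#' Normalize a count matrix for sequencing depth
#'
#' Two size-factor schemes are supported. `median_ratio` (default behind
#' `"auto"`) is the median-of-ratios estimator: for every guide with a
#' nonzero count in all samples, divide its count by its geometric mean
#' across samples; a sample's size factor is the median of those ratios.
#' It is robust when many guides drop out, because depleted guides (zero
#' somewhere) never enter the reference set. `total_count` scales each sample
#' to the mean sample depth. `"auto"` tries `median_ratio` and falls back to
#' `total_count` (with a message) when the former is undefined, e.g. a
#' single-sample matrix or no guide detected everywhere.
#'
#' @param cm A [count_matrix()].
#' @param method `"auto"`, `"median_ratio"` or `"total_count"`.
#' @return Object of class `normalized_counts`: `values` (guides x samples,
#'   count / size factor), `size_factors`, `method`, plus the sample sheet
#'   and gene vector carried over.
#' @export
normalize_counts <- function(cm, method = c("auto", "median_ratio",
                                            "total_count")) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  counts <- cm$counts
  if (ncol(counts) < 1L) stop("need at least one sample")

  median_ratio_sf <- function() {
    if (ncol(counts) < 2L) {
      stop("median_ratio needs >= 2 samples; use method = \"total_count\"")
    }
    keep <- rowSums(counts == 0) == 0
    if (!any(keep)) {
      stop("median_ratio undefined: no guide has nonzero counts in all ",
           "samples; use method = \"total_count\"")
    }
    lc <- log(counts[keep, , drop = FALSE])
    log_geo <- rowMeans(lc)
    apply(lc, 2L, function(col) exp(stats::median(col - log_geo)))
  }
  total_count_sf <- function() {
    depth <- colSums(counts)
    if (all(depth == 0)) stop("all samples have zero reads")
    depth / mean(depth)
  }

  sf <- switch(method,
    median_ratio = median_ratio_sf(),
    total_count = total_count_sf(),
    auto = tryCatch(median_ratio_sf(), error = function(e) {
      message("median_ratio undefined (", conditionMessage(e),
              "); falling back to total_count")
      total_count_sf()
    })
  )
  used <- if (method == "auto") {
    if (ncol(counts) >= 2L && any(rowSums(counts == 0) == 0)) "median_ratio"
    else "total_count"
  } else method
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("non-positive size factor")
  structure(
    list(values = sweep(counts, 2L, sf, "/"),
         size_factors = stats::setNames(sf, colnames(counts)),
         method = used, samples = cm$samples, genes = cm$genes),
    class = "normalized_counts"
  )
}

#' Per-guide log2 fold change (T14 vs T0) for one cell line
#'
#' `lfc = log2((mean normalized T14 + pseudocount) /
#'             (mean normalized T0 + pseudocount))`,
#' replicates combined on the normalized-count scale before the ratio
#' (`replicate_mode = "mean_counts"`, default) or as the average of
#' per-replicate-pair LFCs (`"mean_lfc"`, replicates paired by number).
#' The pseudocount bounds the LFC for guides sequenced to zero at T14.
#'
#' @param norm A `normalized_counts` object.
#' @param cell_line Cell line to compute LFCs for.
#' @param pseudocount Added to both timepoint means on the normalized scale.
#' @param replicate_mode `"mean_counts"` or `"mean_lfc"`.
#' @return data.frame of class `guide_lfc`: `guide_id`, `gene`, `is_control`,
#'   `cell_line`, `lfc`, `zscore` (`NA` until [zscore_lfc()] is applied).
#' @export
guide_lfc <- function(norm, cell_line, pseudocount = 1.0,
                      replicate_mode = c("mean_counts", "mean_lfc")) {
  stopifnot(inherits(norm, "normalized_counts"))
  replicate_mode <- match.arg(replicate_mode)
  s <- norm$samples
  sel0 <- s$cell_line == cell_line & s$timepoint == "T0"
  sel14 <- s$cell_line == cell_line & s$timepoint == "T14"
  if (!any(sel0) || !any(sel14)) {
    stop("cell line '", cell_line, "' needs at least one T0 and one T14 sample")
  }
  v0 <- norm$values[, s$sample_id[sel0], drop = FALSE]
  v14 <- norm$values[, s$sample_id[sel14], drop = FALSE]

  if (replicate_mode == "mean_counts") {
    lfc <- log2((rowMeans(v14) + pseudocount) / (rowMeans(v0) + pseudocount))
  } else {
    r0 <- s$replicate[sel0]
    r14 <- s$replicate[sel14]
    common <- intersect(r0, r14)
    if (length(common) == 0L) {
      stop("mean_lfc mode: no replicate numbers shared between T0 and T14 in '",
           cell_line, "'")
    }
    per_rep <- vapply(common, function(r) {
      log2((v14[, match(r, r14)] + pseudocount) /
             (v0[, match(r, r0)] + pseudocount))
    }, numeric(nrow(v0)))
    lfc <- rowMeans(matrix(per_rep, nrow = nrow(v0)))
  }

  ctrl_label <- attr(norm, "control_label")
  out <- data.frame(
    guide_id = rownames(norm$values),
    gene = norm$genes,
    is_control = if (!is.null(ctrl_label)) norm$genes == ctrl_label else FALSE,
    cell_line = cell_line,
    lfc = unname(lfc),
    zscore = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("guide_lfc", "data.frame")
  out
}

#' Z-score guide LFCs within one screen
#'
#' Standardizes each guide's fold change against ALL guides of the same
#' cell line (targeting and non-targeting alike):
#' `z = (lfc - mean(lfc)) / sd(lfc)`, with the n-1 sample standard
#' deviation. Standardizing within each screen puts cell lines on a common
#' scale, which is what makes the downstream viability score comparable
#' across lines.
#'
#' @param lfcs A `guide_lfc` data.frame for a single cell line.
#' @return The same data.frame with `zscore` filled; by construction
#'   `mean(z) == 0` and `sd(z) == 1` up to floating-point error.
#' @export
zscore_lfc <- function(lfcs) {
  if (length(unique(lfcs$cell_line)) != 1L) {
    stop("z-scores are computed within one cell line at a time")
  }
  x <- lfcs$lfc
  if (length(x) < 2L) stop("need >= 2 guides to z-score")
  if (any(!is.finite(x))) stop("non-finite LFC")
  s <- stats::sd(x)
  if (s == 0) stop("all LFCs identical; z-score undefined (sd = 0)")
  lfcs$zscore <- (x - mean(x)) / s
  lfcs
}

#' Gene-level scores: median LFC and CRISPR viability score
#'
#' Collapses guide-level results to genes, per cell line. The gene score is
#' the median log2 fold change of all guides targeting the gene; the CRISPR
#' viability score is the median of their z-scored LFCs. Medians of
#' even-sized guide sets use the mean of the two central values. Controls
#' are aggregated under the control pseudo-gene and flagged. A guide counts
#' as "scoring" when its LFC is at or below the cell line's depletion
#' cutoff.
#'
#' @param lfcs A `guide_lfc` data.frame (one or several cell lines), with
#'   z-scores filled via [zscore_lfc()].
#' @param cutoffs Named numeric vector of per-cell-line LFC cutoffs (negative).
#' @return data.frame of class `gene_scores`: `gene`, `cell_line`,
#'   `gene_score`, `viability_score`, `n_guides`, `n_scoring_guides`,
#'   `is_control`. Genes contributing zero detected guides are absent and
#'   listed in `attr(, "excluded")`.
#' @export
gene_scores <- function(lfcs, cutoffs) {
  if (anyNA(lfcs$zscore)) stop("z-scores missing; run zscore_lfc() first")
  lines <- unique(lfcs$cell_line)
  miss <- setdiff(lines, names(cutoffs))
  if (length(miss) > 0) {
    stop("no LFC cutoff configured for cell line(s): ",
         paste(miss, collapse = ", "))
  }
  keep <- is.finite(lfcs$lfc)
  excluded <- unique(lfcs$gene[!keep])
  lfcs <- lfcs[keep, , drop = FALSE]

  rows <- lapply(split(seq_len(nrow(lfcs)), lfcs$cell_line), function(ix) {
    cl <- lfcs$cell_line[ix[1L]]
    cut <- cutoffs[[cl]]
    f <- factor(lfcs$gene[ix])
    lfc_by <- split(lfcs$lfc[ix], f)
    z_by <- split(lfcs$zscore[ix], f)
    data.frame(
      gene = levels(f),
      cell_line = cl,
      gene_score = vapply(lfc_by, stats::median, numeric(1)),
      viability_score = vapply(z_by, stats::median, numeric(1)),
      n_guides = as.integer(lengths(lfc_by)),
      n_scoring_guides = vapply(lfc_by, function(v) sum(v <= cut),
                                integer(1)),
      is_control = levels(f) %in% lfcs$gene[ix][lfcs$is_control[ix]],
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$cell_line, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_scores", "data.frame")
  attr(out, "excluded") <- setdiff(excluded, out$gene)
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Run the full scoring stage over a count matrix
#'
#' Convenience wrapper: normalization, per-line LFC, within-line z-scoring,
#' and gene-level collapsing, for every cell line in the sample sheet.
#'
#' @param cm A [count_matrix()].
#' @param cutoffs Named per-line LFC cutoffs (see [gene_scores()]).
#' @param control_label Gene label of the non-targeting pseudo-gene.
#' @inheritParams normalize_counts
#' @inheritParams guide_lfc
#' @return List of class `screen_scores`: `guide_lfc` (all lines, z-scored),
#'   `gene_scores`, `normalization` (method + size factors).
#' @export
score_screen <- function(cm, cutoffs, control_label = "NO_TARGET",
                         method = "auto", pseudocount = 1.0,
                         replicate_mode = "mean_counts") {
  norm <- normalize_counts(cm, method = method)
  attr(norm, "control_label") <- control_label
  lines <- unique(cm$samples$cell_line)
  per_line <- lapply(lines, function(cl) {
    zscore_lfc(guide_lfc(norm, cl, pseudocount = pseudocount,
                         replicate_mode = replicate_mode))
  })
  lfcs <- do.call(rbind, per_line)
  class(lfcs) <- c("guide_lfc", "data.frame")
  structure(
    list(guide_lfc = lfcs,
         gene_scores = gene_scores(lfcs, cutoffs),
         normalization = list(method = norm$method,
                              size_factors = norm$size_factors)),
    class = "screen_scores"
  )
}
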