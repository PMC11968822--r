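#' Configuration of the comparative hit filter
#'
#' The comparative filter contrasts several cancer lines against one
#' nonmalignant line. Each line carries its own depletion cutoff on the gene
#' score (a lower-quality screen warrants a milder cutoff, e.g. -0.5 instead
#' of -1), hits must be supported by a minimum number of scoring guides, and
#' the nonmalignant line's response must not be more pronounced than the
#' cancer lines'.
#'
#' @param normal_line Name of the nonmalignant line.
#' @param cancer_lines Character vector of cancer line names.
#' @param lfc_cutoffs Named numeric vector of negative LFC cutoffs, one per
#'   configured line (normal included).
#' @param min_scoring_guides Minimum guides at/below the cutoff (default 2).
#' @param normal_constraint `"gene_level"` (default): the normal line's
#'   viability score must be >= that of every cancer line. `"guide_level"`:
#'   every scoring guide must be less depleted in the normal line than in
#'   each cancer line where it scores.
#' @param scoring_guides_scope `"per_line"` (default): the guide-support rule
#'   must hold in every cancer line; `"pooled"`: guide support is summed over
#'   cancer lines.
#' @param enriched_cutoffs Optional named positive cutoffs for enrichment
#'   calls; defaults to the mirrored `|lfc_cutoffs|`.
#' @return List of class `hit_config`.
#' @export
hit_config <- function(normal_line, cancer_lines, lfc_cutoffs,
                       min_scoring_guides = 2L,
                       normal_constraint = c("gene_level", "guide_level"),
                       scoring_guides_scope = c("per_line", "pooled"),
                       enriched_cutoffs = NULL) {
  normal_constraint <- match.arg(normal_constraint)
  scoring_guides_scope <- match.arg(scoring_guides_scope)
  if (normal_line %in% cancer_lines) {
    stop("normal_line must not be one of cancer_lines")
  }
  lines <- c(normal_line, cancer_lines)
  miss <- setdiff(lines, names(lfc_cutoffs))
  if (length(miss) > 0) {
    stop("lfc_cutoffs missing for: ", paste(miss, collapse = ", "))
  }
  lfc_cutoffs <- lfc_cutoffs[lines]
  if (any(lfc_cutoffs >= 0)) stop("LFC cutoffs must be negative")
  if (min_scoring_guides < 1L) stop("min_scoring_guides must be >= 1")
  if (is.null(enriched_cutoffs)) enriched_cutoffs <- abs(lfc_cutoffs)
  structure(
    list(normal_line = normal_line, cancer_lines = cancer_lines,
         lfc_cutoffs = lfc_cutoffs,
         min_scoring_guides = as.integer(min_scoring_guides),
         normal_constraint = normal_constraint,
         scoring_guides_scope = scoring_guides_scope,
         enriched_cutoffs = enriched_cutoffs),
    class = "hit_config"
  )
}

.wide_by_line <- function(scores, col, genes, lines) {
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(lines),
              dimnames = list(genes, lines))
  sel <- scores$cell_line %in% lines
  m[cbind(match(scores$gene[sel], genes),
          match(scores$cell_line[sel], lines))] <- scores[[col]][sel]
  m
}

#' Call cancer-selective, common-depleted and enriched genes
#'
#' Applies the comparative filter to gene scores across all configured
#' lines. Definitions, applied in order (first match wins, so every gene
#' gets exactly one call):
#'
#' * `common_depleted`: gene score at/below the line's cutoff with enough
#'   scoring guides in ALL lines, the nonmalignant one included — a
#'   pan-essential dependency.
#' * `cancer_selective`: the same depletion condition in every cancer line,
#'   but not in the normal line as a whole, and the normal-line response not
#'   more pronounced than any cancer line's (per `normal_constraint`).
#' * `enriched`: gene score at/above the mirrored positive cutoff in every
#'   cancer line.
#' * `none`: everything else. Non-targeting controls are always `none`.
#'
#' Checking the pan-depleted condition before the selective one is what
#' keeps common essentials — depleted everywhere, with the normal line's
#' z-score sometimes incidentally the least negative — out of the
#' cancer-selective list.
#'
#' Genes missing scores in any configured line are not called and are listed
#' in `attr(, "not_called")`.
#'
#' @param scores A `gene_scores` data.frame covering all configured lines
#'   (or a `screen_scores` list, from which guide LFCs are also taken).
#' @param config A [hit_config()].
#' @param lfcs Guide-level `guide_lfc` data.frame; required for
#'   `normal_constraint = "guide_level"`.
#' @return data.frame of class `hit_table`: `gene`, `call`, `is_control`,
#'   and per-line `gene_score_*`, `viability_*`, `n_scoring_*` columns.
#' @export
call_hits <- function(scores, config, lfcs = NULL) {
  stopifnot(inherits(config, "hit_config"))
  if (inherits(scores, "screen_scores")) {
    if (is.null(lfcs)) lfcs <- scores$guide_lfc
    scores <- scores$gene_scores
  }
  lines <- c(config$normal_line, config$cancer_lines)
  have <- unique(scores$cell_line)
  miss <- setdiff(lines, have)
  if (length(miss) > 0) {
    stop("configured line(s) absent from score table: ",
         paste(miss, collapse = ", "))
  }
  genes <- sort(unique(scores$gene))
  gs <- .wide_by_line(scores, "gene_score", genes, lines)
  vs <- .wide_by_line(scores, "viability_score", genes, lines)
  nsg <- .wide_by_line(scores, "n_scoring_guides", genes, lines)
  is_control <- stats::setNames(logical(length(genes)), genes)
  is_control[scores$gene[scores$is_control]] <- TRUE

  complete <- rowSums(is.na(gs)) == 0
  not_called <- genes[!complete]

  cuts <- config$lfc_cutoffs[lines]
  ecuts <- config$enriched_cutoffs[config$cancer_lines]
  pass_cut <- sweep(gs, 2L, cuts, "<=")
  if (config$scoring_guides_scope == "per_line") {
    pass_guides <- nsg >= config$min_scoring_guides
  } else {
    pooled_ok <- rowSums(nsg[, config$cancer_lines, drop = FALSE]) >=
      config$min_scoring_guides
    pass_guides <- matrix(pooled_ok, nrow = length(genes), ncol = length(lines),
                          dimnames = dimnames(nsg))
    # the normal line keeps its own per-line support requirement
    pass_guides[, config$normal_line] <-
      nsg[, config$normal_line] >= config$min_scoring_guides
  }
  dep <- pass_cut & pass_guides
  dep_cancer <- rowSums(dep[, config$cancer_lines, drop = FALSE]) ==
    length(config$cancer_lines)
  dep_all <- dep_cancer & dep[, config$normal_line]

  if (config$normal_constraint == "gene_level") {
    max_cancer_vs <- apply(vs[, config$cancer_lines, drop = FALSE], 1L, max)
    normal_ok <- vs[, config$normal_line] >= max_cancer_vs
  } else {
    if (is.null(lfcs)) stop("guide_level constraint needs guide LFCs")
    normal_ok <- .guide_level_normal_ok(lfcs, config, genes)
  }

  enr <- sweep(gs[, config$cancer_lines, drop = FALSE], 2L, ecuts, ">=")
  enr_all <- rowSums(enr) == length(config$cancer_lines)

  # genes missing a line produce NA conditions; they are dropped below
  for (v in c("dep_cancer", "dep_all", "normal_ok", "enr_all")) {
    x <- get(v)
    x[is.na(x)] <- FALSE
    assign(v, x)
  }

  call <- rep("none", length(genes))
  call[dep_all] <- "common_depleted"
  call[!dep_all & dep_cancer & normal_ok] <- "cancer_selective"
  call[call == "none" & enr_all] <- "enriched"
  call[is_control] <- "none"
  call[!complete] <- NA_character_

  out <- data.frame(gene = genes, call = call,
                    is_control = unname(is_control),
                    stringsAsFactors = FALSE)
  for (cl in lines) {
    out[[paste0("gene_score_", cl)]] <- gs[, cl]
    out[[paste0("viability_", cl)]] <- vs[, cl]
    out[[paste0("n_scoring_", cl)]] <- nsg[, cl]
  }
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  attr(out, "not_called") <- not_called
  attr(out, "config") <- config
  out
}

# Strict per-guide reading of the normal constraint: each guide scoring in a
# cancer line must be less depleted in the normal line than in that line.
.guide_level_normal_ok <- function(lfcs, config, genes) {
  lines <- c(config$normal_line, config$cancer_lines)
  gids <- sort(unique(lfcs$guide_id))
  lmat <- matrix(NA_real_, nrow = length(gids), ncol = length(lines),
                 dimnames = list(gids, lines))
  sel <- lfcs$cell_line %in% lines
  lmat[cbind(match(lfcs$guide_id[sel], gids),
             match(lfcs$cell_line[sel], lines))] <- lfcs$lfc[sel]
  gene_of <- stats::setNames(lfcs$gene, lfcs$guide_id)[gids]

  ok <- stats::setNames(rep(TRUE, length(genes)), genes)
  for (cl in config$cancer_lines) {
    cut <- config$lfc_cutoffs[[cl]]
    scoring <- !is.na(lmat[, cl]) & lmat[, cl] <= cut
    viol <- scoring & !(lmat[, config$normal_line] > lmat[, cl])
    bad_genes <- unique(gene_of[viol])
    ok[names(ok) %in% bad_genes] <- FALSE
  }
  unname(ok[genes])
}

#' Rank genes by viability score
#'
#' Stable ascending sort by viability score (most depleted first), ties
#' broken by gene score, then by symbol. With `line` given, ranks that
#' line's scores; otherwise ranks the mean viability score across
#' `cancer_lines` (aggregate mode).
#'
#' @param scores A `gene_scores` data.frame.
#' @param line Single cell line to rank within (optional).
#' @param cancer_lines Lines averaged in aggregate mode (required when
#'   `line` is `NULL`).
#' @param k Number of genes to extract at each extreme; larger than the
#'   table returns everything.
#' @return List: `ranked` (full ordered data.frame with `rank`),
#'   `top_depleted`, `top_enriched`.
#' @export
rank_genes <- function(scores, line = NULL, cancer_lines = NULL, k = 5L) {
  if (!is.null(line)) {
    d <- scores[scores$cell_line == line,
                c("gene", "gene_score", "viability_score"), drop = FALSE]
  } else {
    if (is.null(cancer_lines)) stop("give either `line` or `cancer_lines`")
    sel <- scores[scores$cell_line %in% cancer_lines, , drop = FALSE]
    genes <- sort(unique(sel$gene))
    vs <- .wide_by_line(sel, "viability_score", genes, cancer_lines)
    gsc <- .wide_by_line(sel, "gene_score", genes, cancer_lines)
    d <- data.frame(gene = genes, gene_score = rowMeans(gsc),
                    viability_score = rowMeans(vs), stringsAsFactors = FALSE)
    d <- d[stats::complete.cases(d), , drop = FALSE]
  }
  ord <- order(d$viability_score, d$gene_score, d$gene)
  d <- d[ord, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  k <- min(k, nrow(d))
  list(ranked = d,
       top_depleted = utils::head(d, k),
       top_enriched = utils::tail(d, k)[rev(seq_len(k)), , drop = FALSE])
}

#' Write a hit table to TSV
#'
#' @param hits A `hit_table` from [call_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(inherits(hits, "hit_table"))
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
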