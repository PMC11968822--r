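#' Configuration of the synthetic dropout screen
#'
#' Generative model of a pooled knockout screen across one nonmalignant and
#' several cancer lines, sampled at T0 and after `doublings` population
#' doublings in replicate. The model composes, per guide i in line l:
#'
#' * T0 relative abundance `p_i` proportional to `lognormal(0, t0_dispersion^2)`
#'   (amplified-library representation skew, shared by all samples);
#' * T14 relative abundance proportional to `p_i * 2^(d * f_{gl} * e_i)`,
#'   renormalized per sample, where `f` is the gene's per-doubling log2
#'   growth deficit in that line (<= 0 for depletion) and `e` its guide's
#'   efficacy, Beta-distributed in `[0, 1]`;
#' * observed counts negative-binomial with mean `depth * abundance` and a
#'   single shared dispersion (`Poisson` at `nb_dispersion = 0`),
#'   independent across replicates.
#'
#' Gene classes: `core_essential` (depleted in all lines),
#' `cancer_selective` (depleted only in cancer lines), `enriched` (positive
#' growth effect), remainder `neutral` (f = 0 everywhere). Infection
#' multiplicity, selection and PCR bottlenecks are not modeled explicitly;
#' their noise is absorbed by `nb_dispersion`.
#'
#' @param n_genes Number of targeting genes.
#' @param guides_per_gene Guides designed per gene (>= 1).
#' @param n_controls Non-targeting control guides.
#' @param cell_lines All line names (normal first by convention).
#' @param normal_line Which of `cell_lines` is the nonmalignant line.
#' @param replicates Replicates per (line, timepoint).
#' @param doublings Population doublings between T0 and the endpoint.
#' @param coverage Reads per library guide per sample; `depth` overrides.
#' @param depth Total reads per sample (default `coverage * total guides`).
#' @param t0_dispersion Lognormal sigma of T0 representation skew.
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param efficacy_beta Length-2 shape parameters of the guide-efficacy Beta.
#' @param class_fractions Named fractions for `core_essential`,
#'   `cancer_selective`, `enriched` (must sum to <= 1; rest neutral).
#' @param effect_sizes Named per-doubling log2 growth effects per class.
#' @param control_label Gene label for non-targeting controls.
#' @param spacer_len Spacer length of simulated guides.
#' @param seed Integer seed making every stage reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, guides_per_gene = 4L,
                       n_controls = 50L,
                       cell_lines = c("normal", "cancer_1", "cancer_2",
                                      "cancer_3"),
                       normal_line = "normal",
                       replicates = 3L, doublings = 14,
                       coverage = 500, depth = NULL,
                       t0_dispersion = 0.5, nb_dispersion = 0.05,
                       efficacy_beta = c(9, 1),
                       class_fractions = c(core_essential = 0.10,
                                           cancer_selective = 0.05,
                                           enriched = 0.02),
                       effect_sizes = c(core_essential = -1,
                                        cancer_selective = -1,
                                        enriched = 0.3),
                       control_label = "NO_TARGET", spacer_len = 20L,
                       seed = 1L) {
  if (guides_per_gene < 1L) stop("guides_per_gene must be >= 1")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (doublings <= 0) stop("doublings must be > 0")
  if (!normal_line %in% cell_lines) stop("normal_line must be a cell line")
  stopifnot(all(c("core_essential", "cancer_selective", "enriched") %in%
                  names(class_fractions)))
  if (sum(class_fractions) > 1) stop("class fractions must sum to <= 1")
  n_guides <- n_genes * guides_per_gene + n_controls
  if (is.null(depth)) depth <- coverage * n_guides
  if (depth <= 0) stop("depth must be > 0")
  structure(
    list(n_genes = as.integer(n_genes),
         guides_per_gene = as.integer(guides_per_gene),
         n_controls = as.integer(n_controls),
         cell_lines = cell_lines, normal_line = normal_line,
         cancer_lines = setdiff(cell_lines, normal_line),
         replicates = as.integer(replicates), doublings = doublings,
         depth = depth, t0_dispersion = t0_dispersion,
         nb_dispersion = nb_dispersion, efficacy_beta = efficacy_beta,
         class_fractions = class_fractions, effect_sizes = effect_sizes,
         control_label = control_label, spacer_len = as.integer(spacer_len),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

.rand_spacers <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a guide library manifest
#'
#' Random distinct spacers over a manifest shaped like a genome-wide
#' knockout library at reduced scale: `guides_per_gene` guides per gene plus
#' non-targeting controls. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A `guide_manifest`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes * config$guides_per_gene + config$n_controls
  spacers <- .rand_spacers(n, config$spacer_len)
  for (try in seq_len(10L)) {
    dup <- duplicated(spacers)
    if (!any(dup)) break
    spacers[dup] <- .rand_spacers(sum(dup), config$spacer_len)
  }
  if (anyDuplicated(spacers)) stop("could not generate distinct spacers")
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  records <- data.frame(
    guide_id = c(paste0(rep(genes, each = config$guides_per_gene), "_g",
                        rep(seq_len(config$guides_per_gene), config$n_genes)),
                 sprintf("CTRL%04d", seq_len(config$n_controls))),
    spacer = spacers,
    gene = c(rep(genes, each = config$guides_per_gene),
             rep(config$control_label, config$n_controls)),
    stringsAsFactors = FALSE
  )
  as_manifest(records, control_label = config$control_label,
              spacer_len = config$spacer_len)
}

#' Assign ground-truth classes, fitness effects and guide efficacies
#'
#' Genes are shuffled and sliced into classes by `class_fractions`.
#' Per-(gene, line) fitness: core-essential and enriched effects apply in
#' every line, cancer-selective effects only in cancer lines (fitness 0 in
#' the normal line), neutral genes 0 everywhere. Targeting guides draw a
#' Beta efficacy; controls have efficacy 0.
#'
#' @param manifest A `guide_manifest` (from [simulate_library()]).
#' @param config A [sim_config()].
#' @return List of class `sim_truth`: `genes` (data.frame gene/class),
#'   `fitness` (gene x line matrix), `efficacy` (named per-guide vector).
#' @export
simulate_truth <- function(manifest, config) {
  stopifnot(inherits(manifest, "guide_manifest"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- setdiff(names(manifest$gene_index), manifest$control_label)
  n <- length(genes)
  counts <- vapply(config$class_fractions, function(f) round(f * n),
                   numeric(1))
  shuffled <- sample(genes)
  cls <- rep("neutral", n)
  names(cls) <- shuffled
  at <- 0L
  for (cl in names(counts)) {
    if (counts[[cl]] > 0) {
      cls[seq_len(counts[[cl]]) + at] <- cl
      at <- at + counts[[cl]]
    }
  }
  cls <- cls[genes]

  fitness <- matrix(0, nrow = n, ncol = length(config$cell_lines),
                    dimnames = list(genes, config$cell_lines))
  es <- config$effect_sizes
  fitness[cls == "core_essential", ] <- es[["core_essential"]]
  fitness[cls == "enriched", ] <- es[["enriched"]]
  fitness[cls == "cancer_selective", config$cancer_lines] <-
    es[["cancer_selective"]]

  rec <- manifest$records
  eff <- stats::setNames(numeric(nrow(rec)), rec$guide_id)
  targeting <- !rec$is_control
  eff[targeting] <- stats::rbeta(sum(targeting), config$efficacy_beta[1],
                                 config$efficacy_beta[2])
  structure(
    list(genes = data.frame(gene = genes, class = unname(cls),
                            stringsAsFactors = FALSE),
         fitness = fitness, efficacy = eff),
    class = "sim_truth"
  )
}

#' Expected relative guide abundances under the model
#'
#' Deterministic part of the simulator: per cell line, the T0 abundance
#' vector and the renormalized endpoint abundances after `doublings`
#' doublings of per-guide growth `2^(d * f * e)`. Every column sums to 1.
#'
#' @param p0 T0 relative abundances (sums to 1), named by guide.
#' @param manifest,truth,config As in [simulate_counts()].
#' @return Matrix guides x (line:timepoint) of relative abundances.
#' @export
expected_abundance <- function(p0, manifest, truth, config) {
  rec <- manifest$records
  f_line <- function(cl) {
    f <- rep(0, nrow(rec))
    tg <- !rec$is_control
    f[tg] <- truth$fitness[rec$gene[tg], cl]
    f
  }
  cols <- lapply(config$cell_lines, function(cl) {
    w <- p0 * 2^(config$doublings * f_line(cl) * truth$efficacy[rec$guide_id])
    cbind(T0 = p0, T14 = w / sum(w))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste(rep(config$cell_lines, each = 2L),
                         c("T0", "T14"), sep = ":")
  rownames(out) <- rec$guide_id
  out
}

#' Simulate screen counts for all samples
#'
#' Draws the T0 representation skew once (library property shared across
#' lines), computes per-line endpoint abundances via [expected_abundance()],
#' and samples independent counts per replicate: negative binomial with mean
#' `depth * abundance` and size `1 / nb_dispersion`, or Poisson when the
#' dispersion is 0. Deterministic under the config seed.
#'
#' @param manifest A `guide_manifest`.
#' @param truth A `sim_truth` covering all guides.
#' @param config A [sim_config()].
#' @return A [count_matrix()] with samples named `<line>_<tp>_R<rep>`.
#' @export
simulate_counts <- function(manifest, truth, config) {
  stopifnot(inherits(manifest, "guide_manifest"),
            inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  rec <- manifest$records
  if (!all(rec$guide_id %in% names(truth$efficacy))) {
    stop("truth does not cover all guides")
  }
  set.seed(config$seed + 3L)
  n <- nrow(rec)
  p0_raw <- stats::rlnorm(n, meanlog = 0, sdlog = config$t0_dispersion)
  p0 <- p0_raw / sum(p0_raw)
  ab <- expected_abundance(p0, manifest, truth, config)

  samples <- expand.grid(replicate = seq_len(config$replicates),
                         timepoint = c("T0", "T14"),
                         cell_line = config$cell_lines,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("cell_line", "timepoint", "replicate")]
  samples$sample_id <- sprintf("%s_%s_R%d", samples$cell_line,
                               samples$timepoint, samples$replicate)

  draw <- function(mu) {
    if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu), lambda = mu)
    }
  }
  counts <- vapply(seq_len(nrow(samples)), function(j) {
    mu <- config$depth *
      ab[, paste(samples$cell_line[j], samples$timepoint[j], sep = ":")]
    as.integer(draw(mu))
  }, integer(n))
  dimnames(counts) <- list(rec$guide_id, samples$sample_id)
  count_matrix(counts, samples, genes = rec$gene)
}

#' Simulate a complete screen
#'
#' Orchestrates [simulate_library()], [simulate_truth()] and
#' [simulate_counts()] under one config.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_screen`: `manifest`, `truth`, `counts`,
#'   `config`.
#' @export
simulate_screen <- function(config = sim_config()) {
  manifest <- simulate_library(config)
  truth <- simulate_truth(manifest, config)
  counts <- simulate_counts(manifest, truth, config)
  structure(list(manifest = manifest, truth = truth, counts = counts,
                 config = config),
            class = "sim_screen")
}

#' Emit a FASTQ file realizing one count column
#'
#' Writes exactly `counts[i]` reads per guide: a random stagger prefix
#' (length cycled through `stagger_lengths`, emulating mixed-stagger
#' amplicon primers), the vector barcode, the guide spacer, and a fixed
#' scaffold suffix; qualities are all `I`. Prefixes are re-drawn in the rare
#' case they would create an earlier barcode occurrence, so
#' [count_guides()] on the output reproduces the column exactly.
#'
#' @param counts Named integer vector (guide_id -> count), e.g. one column
#'   of a [count_matrix()].
#' @param manifest The `guide_manifest` the counts refer to.
#' @param path Output FASTQ path (`.gz` compresses).
#' @param stagger_lengths Integer stagger lengths to cycle through.
#' @param barcode Vector barcode preceding the spacer.
#' @param scaffold Fixed suffix after the spacer.
#' @param seed Optional seed for the stagger bases.
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(counts, manifest, path, stagger_lengths = 0:7,
                           barcode = "GAAACACCG",
                           scaffold = "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC",
                           seed = NULL) {
  stopifnot(inherits(manifest, "guide_manifest"))
  if (!is.null(seed)) set.seed(seed)
  counts <- counts[!is.na(counts) & counts > 0]
  rows <- match(names(counts), manifest$records$guide_id)
  if (anyNA(rows)) stop("counts name guides absent from the manifest")
  spacers <- rep(manifest$records$spacer[rows], counts)
  n <- length(spacers)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (n == 0L) {
    return(invisible(path))  # valid empty FASTQ
  }
  stag_len <- rep_len(stagger_lengths, n)
  prefix <- vapply(stag_len, function(L) {
    if (L == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  seqs <- paste0(prefix, barcode, spacers, scaffold)
  # guarantee the first barcode hit is the planted one
  bad <- which(regexpr(barcode, seqs, fixed = TRUE) != stag_len + 1L)
  while (length(bad) > 0) {
    prefix[bad] <- vapply(stag_len[bad], function(L) {
      if (L == 0L) return("")
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    seqs[bad] <- paste0(prefix[bad], barcode, spacers[bad], scaffold)
    bad <- bad[regexpr(barcode, seqs[bad], fixed = TRUE) != stag_len[bad] + 1L]
  }
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- sprintf("@sim_%06d", seq_len(n))
  out[seq(2L, by = 4L, length.out = n)] <- seqs
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- strrep("I", nchar(seqs))
  writeLines(out, con)
  invisible(path)
}

#' Compare called hits with simulation truth
#'
#' Per-class precision and recall of the hit calls against the planted
#' classes (`cancer_selective` vs planted cancer-selective genes,
#' `common_depleted` vs planted core essentials, `enriched` vs planted
#' enriched), plus the full truth-by-call confusion table. When gene scores
#' are supplied, adds the per-cancer-line ROC-AUC separating planted
#' core-essential genes from planted neutral genes on the viability score
#' axis of simulated truth.
#'
#' Precision is `NA` when a class is never called.
#'
#' @param hits A `hit_table` from [call_hits()].
#' @param truth A `sim_truth`.
#' @param scores Optional `gene_scores` for the AUC block.
#' @return List of class `recovery_report`: `per_class` data.frame
#'   (class, n_true, n_called, tp, precision, recall), `confusion` table,
#'   optionally `auc` (data.frame cell_line/auc).
#' @export
recovery_report <- function(hits, truth, scores = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  targets <- hits$gene[!hits$is_control]
  shared <- intersect(targets, truth$genes$gene)
  if (length(shared) == 0L) stop("hit table and truth share no genes")
  truth_cls <- stats::setNames(truth$genes$class, truth$genes$gene)[shared]
  call <- stats::setNames(hits$call, hits$gene)[shared]
  map <- c(core_essential = "common_depleted",
           cancer_selective = "cancer_selective",
           enriched = "enriched", neutral = "none")
  truth_call <- unname(map[truth_cls])

  per_class <- do.call(rbind, lapply(
    c("cancer_selective", "common_depleted", "enriched"), function(cl) {
      n_true <- sum(truth_call == cl)
      n_called <- sum(call == cl)
      tp <- sum(call == cl & truth_call == cl)
      data.frame(class = cl, n_true = n_true, n_called = n_called, tp = tp,
                 precision = if (n_called > 0) tp / n_called else NA_real_,
                 recall = if (n_true > 0) tp / n_true else NA_real_,
                 stringsAsFactors = FALSE)
    }))

  out <- list(per_class = per_class,
              confusion = table(truth = truth_call, call = call))
  if (!is.null(scores)) {
    ess <- truth$genes$gene[truth$genes$class == "core_essential"]
    neu <- truth$genes$gene[truth$genes$class == "neutral"]
    sets <- reference_gene_sets(ess, neu)
    lines <- setdiff(unique(scores$cell_line), character(0))
    aucs <- vapply(lines, function(cl) {
      roc_auc(scores[scores$cell_line == cl, , drop = FALSE], sets,
              score_col = "viability_score")$auc
    }, numeric(1))
    out$auc <- data.frame(cell_line = lines, auc = unname(aucs),
                          stringsAsFactors = FALSE)
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery vs simulation truth:\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Write simulated screen inputs to a directory
#'
#' Materializes a [simulate_screen()] result as the plain-text inputs a real
#' run would start from: `manifest.tsv`, `counts.tsv`, `truth.tsv`,
#' `sample_sheet.csv`.
#'
#' @param sim A `sim_screen`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_screen <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  truth_tab <- data.frame(gene = sim$truth$genes$gene,
                          class = sim$truth$genes$class,
                          sim$truth$fitness[sim$truth$genes$gene, ,
                                            drop = FALSE],
                          check.names = FALSE, stringsAsFactors = FALSE)
  write.table(truth_tab, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$counts$samples, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
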