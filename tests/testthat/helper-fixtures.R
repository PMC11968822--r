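# Shared fixture builders: everything is generated in code at test time.

# deterministic distinct 20-mers: integer i encoded in base 4 over ACGT
int_spacer <- function(i, len = 20L) {
  base <- c("A", "C", "G", "T")
  digits <- matrix(0L, nrow = length(i), ncol = len)
  x <- as.integer(i)
  for (k in seq_len(len)) {
    digits[, k] <- x %% 4L
    x <- x %/% 4L
  }
  apply(digits, 1L, function(d) paste(base[d + 1L], collapse = ""))
}

toy_manifest <- function(n_genes = 2L, guides_per_gene = 2L, n_controls = 1L,
                         control_label = "NO_TARGET") {
  genes <- sprintf("GENE%d", seq_len(n_genes))
  n <- n_genes * guides_per_gene + n_controls
  records <- data.frame(
    guide_id = c(paste0(rep(genes, each = guides_per_gene), "_g",
                        rep(seq_len(guides_per_gene), n_genes)),
                 sprintf("ctrl%d", seq_len(n_controls))),
    spacer = int_spacer(seq_len(n)),
    gene = c(rep(genes, each = guides_per_gene),
             rep(control_label, n_controls)),
    stringsAsFactors = FALSE
  )
  as_manifest(records, control_label = control_label)
}

toy_sheet <- function(lines = "L1", timepoints = c("T0", "T14"),
                      replicates = 1L) {
  g <- expand.grid(replicate = seq_len(replicates), timepoint = timepoints,
                   cell_line = lines, stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_R%d", g$cell_line, g$timepoint, g$replicate)
  sample_sheet(g[, c("sample_id", "cell_line", "timepoint", "replicate")])
}

toy_counts <- function(mat, manifest, sheet) {
  rownames(mat) <- manifest$records$guide_id
  colnames(mat) <- sheet$sample_id
  count_matrix(mat, sheet, genes = manifest$records$gene)
}

# guide_lfc-shaped frame built directly from numbers (for scoring tests)
lfc_frame <- function(lfc, gene, cell_line = "L1", guide_id = NULL,
                      is_control = FALSE, zscore = NULL) {
  d <- data.frame(
    guide_id = guide_id %||% sprintf("g%03d", seq_along(lfc)),
    gene = gene, is_control = is_control, cell_line = cell_line,
    lfc = lfc, zscore = zscore %||% NA_real_, stringsAsFactors = FALSE
  )
  class(d) <- c("guide_lfc", "data.frame")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_cutoffs <- c(normal = -1, cancer_1 = -1, cancer_2 = -1,
                     cancer_3 = -0.5)

default_hit_config <- function(...) {
  hit_config("normal", c("cancer_1", "cancer_2", "cancer_3"),
             default_cutoffs, ...)
}
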