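#' Read a YAML run configuration
#'
#' A run config carries the sample sheet and the comparative hit-filter
#' settings:
#'
#' ```yaml
#' samples:
#'   - {sample_id: normal_T0_R1, cell_line: normal, timepoint: T0,
#'      replicate: 1, fastq: reads/normal_T0_R1.fastq.gz}
#' hit_calling:
#'   normal_line: normal
#'   cancer_lines: [cancer_1, cancer_2, cancer_3]
#'   lfc_cutoffs: {normal: -1, cancer_1: -1, cancer_2: -1, cancer_3: -0.5}
#'   min_scoring_guides: 2
#'   normal_constraint: gene_level
#' ```
#'
#' @param path Path to the YAML file.
#' @return List: `samples` (validated [sample_sheet()]) and, when the
#'   `hit_calling` block is present, `hit_config` (a [hit_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$samples)) {
    out$samples <- sample_sheet(
      do.call(rbind, lapply(cfg$samples, function(s) {
        as.data.frame(s, stringsAsFactors = FALSE)
      }))
    )
  }
  hc <- cfg$hit_calling
  if (!is.null(hc)) {
    out$hit_config <- hit_config(
      normal_line = hc$normal_line,
      cancer_lines = unlist(hc$cancer_lines),
      lfc_cutoffs = unlist(hc$lfc_cutoffs),
      min_scoring_guides = hc$min_scoring_guides %||% 2L,
      normal_constraint = hc$normal_constraint %||% "gene_level",
      scoring_guides_scope = hc$scoring_guides_scope %||% "per_line"
    )
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
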