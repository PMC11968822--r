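#' Build a guide library manifest from a records table
#'
#' A manifest holds the guide library every other step consumes: one row per
#' guide with its unique id, fixed-length spacer sequence, and target gene.
#' Non-targeting controls are identified by a reserved gene label so they stay
#' addressable as a pseudo-gene throughout scoring.
#'
#' @param records data.frame with columns `guide_id`, `spacer`, `gene`.
#' @param control_label Gene label marking non-targeting control guides.
#' @param spacer_len Required spacer length in nucleotides.
#' @param on_duplicate_spacer `"error"` (default) or `"warn"`; quantification
#'   relies on an exact spacer-to-guide map, so duplicate spacers are rejected
#'   unless explicitly downgraded (first occurrence then wins).
#' @return An object of class `guide_manifest`: list with `records` (the
#'   validated data.frame, plus a logical `is_control` column), `spacer_index`
#'   (named character, spacer -> guide_id), `gene_index` (gene -> guide ids),
#'   `control_label` and `spacer_len`.
#' @export
as_manifest <- function(records, control_label = "NO_TARGET", spacer_len = 20L,
                        on_duplicate_spacer = c("error", "warn")) {
  on_duplicate_spacer <- match.arg(on_duplicate_spacer)
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  required <- c("guide_id", "spacer", "gene")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  records <- data.frame(
    guide_id = as.character(records$guide_id),
    spacer   = toupper(as.character(records$spacer)),
    gene     = as.character(records$gene),
    stringsAsFactors = FALSE
  )
  if (anyNA(records$guide_id) || any(!nzchar(records$guide_id))) {
    stop("guide_id must be non-empty for every row")
  }
  dup_id <- unique(records$guide_id[duplicated(records$guide_id)])
  if (length(dup_id) > 0) {
    stop("duplicate guide_id: ", paste(utils::head(dup_id, 5L), collapse = ", "))
  }
  bad_len <- which(nchar(records$spacer) != spacer_len)
  if (length(bad_len) > 0) {
    stop(sprintf("spacer length != %d at row %d (guide '%s')",
                 spacer_len, bad_len[1L], records$guide_id[bad_len[1L]]))
  }
  bad_alpha <- which(grepl("[^ACGT]", records$spacer))
  if (length(bad_alpha) > 0) {
    stop(sprintf("non-ACGT spacer at row %d (guide '%s'): %s",
                 bad_alpha[1L], records$guide_id[bad_alpha[1L]],
                 records$spacer[bad_alpha[1L]]))
  }
  dup_sp <- which(duplicated(records$spacer))
  if (length(dup_sp) > 0) {
    msg <- sprintf("duplicate spacer at row %d (guide '%s')",
                   dup_sp[1L], records$guide_id[dup_sp[1L]])
    if (on_duplicate_spacer == "error") {
      stop(msg, "; pass on_duplicate_spacer = \"warn\" to keep first occurrence")
    }
    warning(msg, "; keeping first occurrence in the spacer index")
  }
  records$is_control <- records$gene == control_label

  first <- !duplicated(records$spacer)
  spacer_index <- records$guide_id[first]
  names(spacer_index) <- records$spacer[first]

  structure(
    list(
      records = records,
      spacer_index = spacer_index,
      gene_index = split(records$guide_id, records$gene),
      control_label = control_label,
      spacer_len = as.integer(spacer_len)
    ),
    class = "guide_manifest"
  )
}

#' @export
print.guide_manifest <- function(x, ...) {
  cat(sprintf("guide_manifest: %d guides (%d targeting, %d controls), %d genes\n",
              nrow(x$records), sum(!x$records$is_control),
              sum(x$records$is_control),
              length(setdiff(names(x$gene_index), x$control_label))))
  invisible(x)
}

.manifest_delim <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a guide library manifest from TSV/CSV
#'
#' The delimiter is auto-detected from the file extension (`.csv` = comma,
#' anything else = tab). Column names can be remapped for files using other
#' headers.
#'
#' @param path Path to the manifest file (header row required).
#' @param columns Named character vector mapping the canonical names
#'   `guide_id`, `spacer`, `gene` to the column names used in the file.
#' @inheritParams as_manifest
#' @return A [as_manifest()] `guide_manifest`.
#' @export
read_manifest <- function(path,
                          columns = c(guide_id = "guide_id", spacer = "spacer",
                                      gene = "gene"),
                          control_label = "NO_TARGET", spacer_len = 20L,
                          on_duplicate_spacer = c("error", "warn")) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  tab <- read.delim(path, sep = .manifest_delim(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(columns), names(tab))
  if (length(miss) > 0) {
    stop("manifest file lacks column(s): ", paste(miss, collapse = ", "))
  }
  records <- data.frame(
    guide_id = tab[[columns[["guide_id"]]]],
    spacer   = tab[[columns[["spacer"]]]],
    gene     = tab[[columns[["gene"]]]],
    stringsAsFactors = FALSE
  )
  as_manifest(records, control_label = control_label, spacer_len = spacer_len,
              on_duplicate_spacer = on_duplicate_spacer)
}

#' Write a manifest back to TSV/CSV
#'
#' Inverse of [read_manifest()]: writing then reading reproduces the records
#' field-for-field.
#'
#' @param manifest A `guide_manifest`.
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "guide_manifest"))
  out <- manifest$records[, c("guide_id", "spacer", "gene")]
  write.table(out, path, sep = .manifest_delim(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Summarize manifest composition
#'
#' Accounting report over a manifest: totals, targeting/control split, gene
#' count and guides-per-gene histogram. Reports rather than raises; an empty
#' manifest yields a warning and zero totals. Always satisfies
#' `n_targeting + n_controls == n_total`.
#'
#' @param manifest A `guide_manifest`.
#' @return List of class `manifest_report` with `n_total`, `n_targeting`,
#'   `n_controls`, `n_genes` (targeting genes only), `guides_per_gene`
#'   (named table) and `violations` (character vector, empty when clean).
#' @export
validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "guide_manifest"))
  rec <- manifest$records
  violations <- character(0)
  if (nrow(rec) == 0L) {
    warning("manifest is empty")
    violations <- c(violations, "manifest contains no guides")
  }
  targeting <- rec[!rec$is_control, , drop = FALSE]
  gpg <- if (nrow(targeting) > 0) table(targeting$gene) else table(character(0))
  structure(
    list(
      n_total = nrow(rec),
      n_targeting = nrow(targeting),
      n_controls = sum(rec$is_control),
      n_genes = length(unique(targeting$gene)),
      guides_per_gene = gpg,
      violations = violations
    ),
    class = "manifest_report"
  )
}

#' @export
print.manifest_report <- function(x, ...) {
  cat(sprintf("manifest report: %d guides = %d targeting + %d controls; %d genes\n",
              x$n_total, x$n_targeting, x$n_controls, x$n_genes))
  if (length(x$violations) > 0) {
    cat("violations:\n", paste(" -", x$violations, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read a gene list (one symbol per line)
#'
#' Lines may carry `#` comments; surrounding whitespace is stripped and
#' duplicates are dropped. The result is order-independent (sorted).
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- unique(lines[nzchar(lines)])
  if (length(genes) == 0L) stop("gene list is empty: ", path)
  sort(genes)
}

#' Bundle reference essential/nonessential gene sets
#'
#' Reference sets play the role of positives and negatives in screen QC:
#' a broad fitness/essential set, a nonessential set, and optionally a
#' core-essential subset. Essential and nonessential sets must be disjoint.
#'
#' @param essential,nonessential Character vectors of gene symbols (or single
#'   file paths, read via [read_gene_list()]).
#' @param core_essential Optional character vector (or path) with the
#'   core-essential subset.
#' @return List of class `reference_gene_sets`.
#' @export
reference_gene_sets <- function(essential, nonessential, core_essential = NULL) {
  as_set <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) read_gene_list(x)
    else sort(unique(as.character(x)))
  }
  essential <- as_set(essential)
  nonessential <- as_set(nonessential)
  overlap <- intersect(essential, nonessential)
  if (length(overlap) > 0) {
    stop("essential and nonessential sets overlap: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  if (!is.null(core_essential)) core_essential <- as_set(core_essential)
  structure(
    list(essential = essential, nonessential = nonessential,
         core_essential = core_essential),
    class = "reference_gene_sets"
  )
}
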