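#' Extract spacer sequences downstream of the vector barcode
#'
#' Pooled-screen amplicons carry the guide spacer immediately after a fixed
#' vector barcode (`GAAACACCG`, the last bases of the U6 promoter region
#' ending in the `G` that starts transcription). The spacer is taken as the
#' `spacer_len` bases following the FIRST exact occurrence of the barcode, so
#' staggered amplicon prefixes of any length are handled without a fixed
#' offset. Reads without the barcode, or truncated before the full spacer,
#' yield `NA`.
#'
#' Matching is exact: no mismatches, and `N` bases never match.
#'
#' @param reads Character vector of read sequences (upper-cased internally).
#' @param barcode Barcode immediately preceding the spacer.
#' @param spacer_len Spacer length to extract.
#' @return Character vector, one spacer or `NA` per read.
#' @export
extract_spacer <- function(reads, barcode = "GAAACACCG", spacer_len = 20L) {
  if (!nzchar(barcode)) stop("`barcode` must be non-empty")
  spacer_len <- as.integer(spacer_len)
  reads <- toupper(as.character(reads))
  pos <- regexpr(barcode, reads, fixed = TRUE)
  start <- as.integer(pos) + nchar(barcode)
  out <- substr(reads, start, start + spacer_len - 1L)
  out[as.integer(pos) < 0L | nchar(out) < spacer_len] <- NA_character_
  out
}

#' Validate a screen sample sheet
#'
#' @param samples data.frame with columns `sample_id`, `cell_line`,
#'   `timepoint` (`"T0"` or `"T14"`), `replicate` (small integer); an optional
#'   `fastq` column carries per-sample read paths.
#' @return The validated data.frame (character/integer typed).
#' @export
sample_sheet <- function(samples) {
  required <- c("sample_id", "cell_line", "timepoint", "replicate")
  miss <- setdiff(required, names(samples))
  if (length(miss) > 0) {
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$cell_line <- as.character(samples$cell_line)
  samples$timepoint <- as.character(samples$timepoint)
  samples$replicate <- as.integer(samples$replicate)
  bad_tp <- setdiff(unique(samples$timepoint), c("T0", "T14"))
  if (length(bad_tp) > 0) {
    stop("timepoint must be T0 or T14; found: ", paste(bad_tp, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample sheet")
  key <- paste(samples$cell_line, samples$timepoint, samples$replicate)
  if (anyDuplicated(key)) {
    stop("(cell_line, timepoint, replicate) must be unique across the run")
  }
  samples
}

#' Construct a guide-by-sample count matrix object
#'
#' @param counts Non-negative integer matrix, guides in rows (rownames =
#'   guide ids), samples in columns (colnames = sample ids).
#' @param samples Sample sheet (see [sample_sheet()]), rows matching columns.
#' @param genes Character vector of gene symbols aligned to the rows.
#' @param totals Optional data.frame with per-sample `total_reads`,
#'   `matched_reads`, `unmatched_reads`; defaults to column sums with zero
#'   unmatched (appropriate for simulated or imported tables).
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, genes, totals = NULL) {
  samples <- sample_sheet(samples)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts must have guide ids as rownames")
  if (!identical(colnames(counts), samples$sample_id)) {
    if (!setequal(colnames(counts), samples$sample_id)) {
      stop("count matrix columns do not match the sample sheet")
    }
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  if (length(genes) != nrow(counts)) stop("`genes` must align with count rows")
  if (is.null(totals)) {
    cs <- colSums(counts)
    totals <- data.frame(sample_id = samples$sample_id, total_reads = cs,
                         matched_reads = cs, unmatched_reads = 0L,
                         row.names = NULL)
  }
  stopifnot(all(totals$matched_reads + totals$unmatched_reads ==
                  totals$total_reads))
  structure(
    list(counts = counts, samples = samples, genes = as.character(genes),
         totals = totals),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples (%d cell lines)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$cell_line))))
  invisible(x)
}

.read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count guides from screen FASTQ reads
#'
#' Single-pass quantifier: each read is reduced to the spacer following the
#' vector barcode ([extract_spacer()]) and matched exactly against the
#' manifest's spacer index. Each read contributes at most 1 to exactly one
#' guide; everything else (no barcode, truncated spacer, spacer absent from
#' the library) is tallied as unmatched. Guides seen in no read are present
#' with count 0. Quality strings are ignored.
#'
#' @param fastq_paths Named character vector, `sample_id -> fastq path`
#'   (plain or gzipped). If omitted, taken from the sample sheet's `fastq`
#'   column. Every name must exist in the sample sheet.
#' @param manifest A `guide_manifest`.
#' @param samples Sample sheet; every sample must have a FASTQ path.
#' @inheritParams extract_spacer
#' @return A [count_matrix()] with per-sample total/matched/unmatched tallies.
#' @export
count_guides <- function(fastq_paths = NULL, manifest, samples,
                         barcode = "GAAACACCG", spacer_len = NULL) {
  stopifnot(inherits(manifest, "guide_manifest"))
  samples <- sample_sheet(samples)
  if (is.null(spacer_len)) spacer_len <- manifest$spacer_len
  if (is.null(fastq_paths)) {
    if (is.null(samples$fastq)) stop("no FASTQ paths given (argument or sheet)")
    fastq_paths <- stats::setNames(as.character(samples$fastq), samples$sample_id)
  }
  unknown <- setdiff(names(fastq_paths), samples$sample_id)
  if (length(unknown) > 0) {
    stop("sample_id not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(samples$sample_id, names(fastq_paths))
  if (length(missing) > 0) {
    stop("no FASTQ path for sample(s): ", paste(missing, collapse = ", "))
  }

  rec <- manifest$records
  n_guides <- nrow(rec)
  counts <- matrix(0L, nrow = n_guides, ncol = nrow(samples),
                   dimnames = list(rec$guide_id, samples$sample_id))
  totals <- data.frame(sample_id = samples$sample_id, total_reads = 0L,
                       matched_reads = 0L, unmatched_reads = 0L)
  for (j in seq_len(nrow(samples))) {
    sid <- samples$sample_id[j]
    seqs <- .read_fastq_seqs(fastq_paths[[sid]])
    spacers <- extract_spacer(seqs, barcode = barcode, spacer_len = spacer_len)
    # match against first occurrence of each spacer, consistent with the index
    idx <- match(spacers, names(manifest$spacer_index))
    hit <- !is.na(idx)
    if (any(hit)) {
      row_of <- match(manifest$spacer_index[idx[hit]], rec$guide_id)
      counts[, j] <- tabulate(row_of, nbins = n_guides)
    }
    totals$total_reads[j] <- length(seqs)
    totals$matched_reads[j] <- sum(hit)
    totals$unmatched_reads[j] <- length(seqs) - sum(hit)
  }
  count_matrix(counts, samples, genes = rec$gene, totals = totals)
}

#' Read/write MAGeCK-style count tables
#'
#' Tab-separated, columns `sgRNA`, `gene`, then one column per sample.
#' Reading reorders sample columns to the sheet and (when a manifest is
#' given) aligns rows to manifest order, filling absent guides with zeros;
#' guides unknown to the manifest, or gene assignments disagreeing with it,
#' are errors. Writing then reading is the identity.
#'
#' @param path File path (TSV).
#' @param samples Sample sheet for the run.
#' @param manifest Optional `guide_manifest` to validate/align against.
#' @return `read_count_table()`: a [count_matrix()] (per-sample totals are
#'   the column sums; read-level tallies are not stored in this format).
#' @export
read_count_table <- function(path, samples, manifest = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("sgRNA", "gene") %in% names(tab))) {
    stop("count table must start with columns sgRNA, gene")
  }
  samples <- sample_sheet(samples)
  miss <- setdiff(samples$sample_id, names(tab))
  if (length(miss) > 0) {
    stop("count table lacks sample column(s): ", paste(miss, collapse = ", "))
  }
  counts <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  rownames(counts) <- tab$sgRNA
  genes <- tab$gene
  if (!is.null(manifest)) {
    rec <- manifest$records
    unknown <- setdiff(tab$sgRNA, rec$guide_id)
    if (length(unknown) > 0) {
      stop("guide(s) in table absent from manifest: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    tab_gene <- stats::setNames(genes, tab$sgRNA)
    shared <- intersect(tab$sgRNA, rec$guide_id)
    man_gene <- stats::setNames(rec$gene, rec$guide_id)[shared]
    bad <- shared[tab_gene[shared] != man_gene]
    if (length(bad) > 0) {
      stop("gene column disagrees with manifest for: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    full <- matrix(0L, nrow = nrow(rec), ncol = ncol(counts),
                   dimnames = list(rec$guide_id, colnames(counts)))
    full[tab$sgRNA, ] <- counts
    counts <- full
    genes <- rec$gene
  }
  count_matrix(counts, samples, genes = genes)
}

#' @rdname read_count_table
#' @param cm A [count_matrix()].
#' @export
write_count_table <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- data.frame(sgRNA = rownames(cm$counts), gene = cm$genes,
                    cm$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
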