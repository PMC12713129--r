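#' Single-cell count container
#'
#' A `cell_counts` object holds a sparse genes x cells integer count
#' matrix together with one annotation row per cell (sample id, timepoint
#' in hours, cell type). Timepoints are stored as real hours so that phase
#' arithmetic stays numeric; whether the clock reference is Zeitgeber or
#' circadian time is carried as a metadata flag only.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, genes in
#'   rows, cells in columns.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   row.
#' @param cells data.frame with columns `barcode`, `sample`,
#'   `timepoint_hours`, `cell_type`; one row per matrix column.
#' @param time_reference `"ZT"` or `"CT"`.
#' @return A validated object of class `cell_counts`.
#' @export
cell_counts <- function(counts, gene_ids, cells, time_reference = "ZT") {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  obj <- structure(list(counts = counts,
                        gene_ids = as.character(gene_ids),
                        cells = as.data.frame(cells),
                        time_reference = match.arg(time_reference,
                                                   c("ZT", "CT"))),
                   class = "cell_counts")
  validate_cell_counts(obj)
}

validate_cell_counts <- function(x) {
  counts <- x$counts
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("cell_counts: matrix must have at least one gene and one cell",
         call. = FALSE)
  if (length(x$gene_ids) != nrow(counts))
    stop("cell_counts: gene_ids length does not match matrix rows",
         call. = FALSE)
  if (anyDuplicated(x$gene_ids))
    stop("cell_counts: duplicate gene ids", call. = FALSE)
  need <- c("barcode", "sample", "timepoint_hours", "cell_type")
  miss <- setdiff(need, names(x$cells))
  if (length(miss))
    stop("cell_counts: cell annotations missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(x$cells) != ncol(counts))
    stop("cell_counts: one annotation row per cell required (",
         nrow(x$cells), " rows for ", ncol(counts), " cells)",
         call. = FALSE)
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != trunc(v))))
    stop("cell_counts: counts must be nonnegative integers", call. = FALSE)
  if (!is.numeric(x$cells$timepoint_hours) ||
      anyNA(x$cells$timepoint_hours))
    stop("cell_counts: timepoint_hours must be numeric and non-missing",
         call. = FALSE)
  rownames(x$counts) <- x$gene_ids
  x
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d genes x %d cells, %d samples, %d cell types (%s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$sample)),
              length(unique(x$cells$cell_type)), x$time_reference))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Subset a `cell_counts` object by cells and/or genes
#'
#' @param x a `cell_counts` object.
#' @param cells logical or integer index over columns.
#' @param genes logical, integer, or character index over rows.
#' @return A `cell_counts` restricted to the selection.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "cell_counts"))
  counts <- x$counts
  ann <- x$cells
  gid <- x$gene_ids
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, gid)
    if (anyNA(genes)) stop("unknown gene id in selection", call. = FALSE)
    counts <- counts[genes, , drop = FALSE]
    gid <- gid[genes]
  }
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
    ann <- ann[cells, , drop = FALSE]
  }
  cell_counts(counts, gid, ann, x$time_reference)
}

#' Read a count matrix with its metadata
#'
#' Reads the on-disk triplet written by [write_counts()]: a Matrix Market
#' coordinate file (genes x cells, 1-based indices per the standard),
#' a cell annotation TSV and a gene TSV. Dimensions are cross-checked and
#' non-integer or negative entries rejected.
#'
#' @param mtx_path path to the `.mtx` file.
#' @param cells_tsv path to the cell annotation TSV (columns `barcode`,
#'   `sample`, `timepoint_hours`, `cell_type`).
#' @param genes_tsv path to the gene TSV (first column `gene_id`).
#' @return A `cell_counts` object; gene-level extra columns (e.g. planted
#'   ground truth) are attached as attribute `"gene_meta"`.
#' @export
read_counts <- function(mtx_path, cells_tsv, genes_tsv) {
  for (p in c(mtx_path, cells_tsv, genes_tsv))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  m <- Matrix::readMM(mtx_path)
  cells <- utils::read.delim(cells_tsv, stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_tsv, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes))
    stop("genes tsv must have a gene_id column", call. = FALSE)
  if (nrow(genes) != nrow(m))
    stop(sprintf("dimension mismatch: %d genes in tsv, %d matrix rows",
                 nrow(genes), nrow(m)), call. = FALSE)
  if (nrow(cells) != ncol(m))
    stop(sprintf("dimension mismatch: %d cell rows, %d matrix columns",
                 nrow(cells), ncol(m)), call. = FALSE)
  out <- cell_counts(m, genes$gene_id, cells)
  attr(out, "gene_meta") <- genes
  out
}

#' Write a count matrix with its metadata
#'
#' @param x a `cell_counts` object.
#' @param dir output directory (created if needed). Writes `counts.mtx`,
#'   `cells.tsv`, `genes.tsv`.
#' @param gene_meta optional data.frame of per-gene columns to store next
#'   to `gene_id` (e.g. simulation ground truth).
#' @return The directory path, invisibly.
#' @export
write_counts <- function(x, dir, gene_meta = NULL) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "counts.mtx"))
  write_results(x$cells, file.path(dir, "cells.tsv"))
  genes <- data.frame(gene_id = x$gene_ids, stringsAsFactors = FALSE)
  if (!is.null(gene_meta)) {
    stopifnot(nrow(gene_meta) == length(x$gene_ids))
    extra <- gene_meta[setdiff(names(gene_meta), "gene_id")]
    genes <- cbind(genes, extra)
  }
  write_results(genes, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Write a result table as TSV
#'
#' Full-precision (17 significant digits) tab-separated output with a
#' header and stable column order. Zero p-values are clamped to the
#' smallest representable double so that downstream `-log10` transforms
#' stay finite; a zero adjusted p is never written.
#'
#' @param table data.frame with at least one column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table), ncol(table) >= 1L)
  tab <- table
  for (col in intersect(c("p", "padj"), names(tab))) {
    v <- tab[[col]]
    v[!is.na(v) & v == 0] <- .Machine$double.xmin
    tab[[col]] <- v
  }
  num <- vapply(tab, is.double, logical(1L))
  tab[num] <- lapply(tab[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA
    out
  })
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read or write a scalar time series
#'
#' Two-column TSV (`time_hours`, `value`), with an optional `replicate`
#' column. Times must be sorted and match the number of values.
#'
#' @param path file path.
#' @return `read_time_series` returns a data.frame validated as a time
#'   series; `write_time_series` returns `path` invisibly.
#' @export
read_time_series <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_time_series(tab)
}

#' @param series data.frame with columns `time_hours`, `value`.
#' @rdname read_time_series
#' @export
write_time_series <- function(series, path) {
  validate_time_series(series)
  write_results(series, path)
}

validate_time_series <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (!all(c("time_hours", "value") %in% names(tab)))
    stop("time series needs columns time_hours and value", call. = FALSE)
  if (is.unsorted(tab$time_hours))
    stop("time series times must be sorted", call. = FALSE)
  if (anyNA(tab$time_hours) || anyNA(tab$value))
    stop("time series must not contain missing values", call. = FALSE)
  tab
}

#' Read or write promoter sequences as FASTA
#'
#' Thin wrappers around `Biostrings`; sequences are handled in-package as
#' named uppercase character vectors over ACGTN.
#'
#' @param path FASTA file path.
#' @return `read_fasta` returns a named character vector;
#'   `write_fasta` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
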