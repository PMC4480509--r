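#' Gene-by-sample count matrix with sample metadata
#'
#' The basic container of the pipeline: a non-negative integer matrix of
#' read counts (rows = genes, columns = samples) together with per-sample
#' metadata. The `group` column holds the cell type, or `"dilution"` for
#' control replicates, in which case `input_pg` records the amount of
#' bulk RNA (in picograms) the amplification started from. Optional QC
#' columns (`total_reads`, `percent_unique`, `percent_short_fragments`)
#' feed the sample filter.
#'
#' @param counts Numeric matrix of non-negative counts with unique
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @param sample_meta `data.frame` with one row per sample. Must contain
#'   `sample_id` matching `colnames(counts)` and `group`; may contain
#'   `input_pg`, `total_reads`, `percent_unique`,
#'   `percent_short_fragments`.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `sample_meta`.
#' @export
count_matrix <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(counts),
                              group = "unknown",
                              stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(sample_meta)))
    stop("sample_meta needs 'sample_id' and 'group' columns")
  if (!identical(sort(sample_meta$sample_id), sort(colnames(counts))))
    stop("sample_meta$sample_id must match colnames(counts)")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:", paste(sprintf("%s (%d)", names(table(x$sample_meta$group)),
                               table(x$sample_meta$group)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read and write count matrices as TSV
#'
#' The TSV layout is genes in rows, a header row of sample ids, and gene
#' ids in the first column. Metadata travels in a separate TSV with
#' columns `sample_id`, `group` and optionally `input_pg` plus QC fields.
#'
#' @param path Path to the counts TSV.
#' @param meta_path Optional path to the metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, meta_path = NULL) {
  tab <- read.delim(path, check.names = FALSE, row.names = 1)
  meta <- if (!is.null(meta_path)) read.delim(meta_path) else NULL
  count_matrix(as.matrix(tab), meta)
}

#' @param x A [count_matrix()].
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as MatrixMarket triplets
#'
#' Writes the `.mtx` file plus one-id-per-line gene and sample name
#' files, the layout [read_counts_mtx()] reads back.
#'
#' @param x A [count_matrix()].
#' @param mtx_path Output `.mtx` path.
#' @param genes_path,samples_path Name-file paths (one id per line).
#' @param meta_path Optional metadata TSV path.
#' @export
write_counts_mtx <- function(x, mtx_path, genes_path, samples_path,
                             meta_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("the Matrix package is required to write MTX output")
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), mtx_path)
  writeLines(rownames(x$counts), genes_path)
  writeLines(colnames(x$counts), samples_path)
  if (!is.null(meta_path))
    write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(mtx_path)
}

#' Read a count matrix stored as MatrixMarket triplets
#'
#' Companion row/column name files hold one gene or sample id per line,
#' in matrix order.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param genes_path,samples_path One-id-per-line name files.
#' @param meta_path Optional metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path,
                            meta_path = NULL) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("the Matrix package is required to read MTX input")
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  meta <- if (!is.null(meta_path)) read.delim(meta_path) else NULL
  count_matrix(m, meta)
}

## Internal accessor: columns belonging to one metadata group.
.group_samples <- function(x, group) {
  x$sample_meta$sample_id[x$sample_meta$group == group]
}
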