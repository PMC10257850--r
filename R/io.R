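# Readers and writers for the formats the pipeline touches: count matrices
# (Matrix Market triplet directories in the 10x dialect, dense CSV/TSV),
# label vectors, embeddings and JSON metric reports.

validate_counts <- function(values, cell_ids, gene_ids) {
  if (length(cell_ids) != nrow(values))
    stop_validation("number of cell ids (", length(cell_ids),
                    ") does not match number of rows (", nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop_validation("number of gene ids (", length(gene_ids),
                    ") does not match number of columns (", ncol(values), ")")
  if (anyDuplicated(cell_ids)) stop_validation("cell ids are not unique")
  if (anyDuplicated(gene_ids)) stop_validation("gene ids are not unique")
  v <- if (inherits(values, "sparseMatrix")) values@x else values
  if (any(v < 0)) stop_validation("count matrix contains negative entries")
  if (!all(is_wholenumber(v))) stop_validation("count matrix contains non-integer entries")
  invisible(TRUE)
}

# Counts are held sparse (dgCMatrix) when fewer than half the entries are
# non-zero, dense base matrix otherwise; every consumer accepts either.
counts_container <- function(values, cell_ids, gene_ids) {
  validate_counts(values, cell_ids, gene_ids)
  dens <- if (inherits(values, "sparseMatrix")) {
    length(values@x) / prod(dim(values))
  } else {
    mean(values != 0)
  }
  values <- if (dens < 0.5) {
    if (inherits(values, "Matrix"))
      methods::as(methods::as(values, "generalMatrix"), "CsparseMatrix")
    else Matrix::Matrix(values, sparse = TRUE)
  } else {
    as_dense(values)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  values
}

#' Read a cells-by-genes count matrix
#'
#' Supports 10x-style Matrix Market directories (`matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv`, stored genes-by-cells and transposed on load) and dense
#' CSV/TSV files with a gene-ID header row and a cell-ID first column.
#'
#' @param path Directory (for `format = "mtx_dir"`) or file path.
#' @param format One of `"mtx_dir"`, `"dense_csv"`, `"dense_tsv"`.
#' @return A cells-by-genes matrix of non-negative integer counts with cell
#'   ids as rownames and gene ids as colnames (sparse `dgCMatrix` when less
#'   than half the entries are non-zero).
#' @export
read_counts <- function(path, format = c("mtx_dir", "dense_csv", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stop_io("directory not found: ", path)
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    cells <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes, cells))
      if (!file.exists(f)) stop_io("missing file: ", f)
    m <- Matrix::readMM(mtx)
    gene_ids <- read.table(genes, sep = "\t", stringsAsFactors = FALSE)[[1]]
    cell_ids <- read.table(cells, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids))
      stop_io("matrix.mtx is ", nrow(m), " x ", ncol(m), " but found ",
              length(gene_ids), " gene ids and ", length(cell_ids), " cell ids")
    counts_container(Matrix::t(m), cell_ids, gene_ids)  # 10x stores genes x cells
  } else {
    if (!file.exists(path)) stop_io("file not found: ", path)
    sep <- if (format == "dense_csv") "," else "\t"
    df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                     check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop_validation("non-numeric entries in ", path)
    counts_container(m, rownames(df), colnames(df))
  }
}

#' Write a cells-by-genes count matrix
#'
#' Inverse of [read_counts()]: the same path/format pair round-trips values
#' and identifiers exactly.
#'
#' @param counts Matrix with cell rownames and gene colnames.
#' @param path Output directory (mtx) or file.
#' @param format As in [read_counts()].
#' @export
write_counts <- function(counts, path, format = c("mtx_dir", "dense_csv", "dense_tsv")) {
  format <- match.arg(format)
  validate_counts(counts, rownames(counts), colnames(counts))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sp <- if (inherits(counts, "Matrix")) counts
          else Matrix::Matrix(as_dense(counts) * 1.0, sparse = TRUE)
    m <- methods::as(methods::as(Matrix::t(sp), "generalMatrix"),
                     "TsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    write.table(colnames(counts), file.path(path, "genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(rownames(counts), file.path(path, "barcodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "dense_csv") "," else "\t"
    df <- as.data.frame(as_dense(counts), check.names = FALSE)
    write.table(data.frame(cell_id = rownames(counts), df, check.names = FALSE),
                path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a latent embedding as TSV
#'
#' One row per cell: `cell_id` column then the numeric coordinates, written
#' at full double precision (round-trips within 1e-12).
#'
#' @param Z Numeric matrix, cells in rows.
#' @param cell_ids Character vector, one id per row of `Z`.
#' @param path Output file.
#' @export
write_embedding <- function(Z, cell_ids, path) {
  Z <- as_dense(Z)
  if (length(cell_ids) != nrow(Z))
    stop_validation("length(cell_ids) != nrow(Z)")
  d <- ncol(Z)
  header <- paste(c("cell_id", paste0("dim", seq_len(max(d, 0)))), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(Z) > 0) {
    body <- apply(format(Z, digits = 17, trim = TRUE, scientific = TRUE), 1,
                  paste, collapse = "\t")
    writeLines(paste(cell_ids, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path TSV file.
#' @return Numeric matrix with cell ids as rownames.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Read / write per-cell label files
#'
#' Two-column TSV `cell_id <TAB> label`.
#' @param labels Vector of labels; @param cell_ids ids, same length.
#' @param path File path.
#' @export
write_labels <- function(labels, cell_ids, path) {
  if (length(labels) != length(cell_ids))
    stop_validation("length(labels) != length(cell_ids)")
  write.table(data.frame(cell_id = cell_ids, label = labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  stats::setNames(df[[2]], df[[1]])
}

#' Write a metrics report as JSON
#'
#' Keys are written in the order given; values must be finite numbers,
#' `NULL`, or nested named lists of such.
#'
#' @param metrics Named list of finite numbers (or named sub-lists).
#' @param path Output `.json` file.
#' @export
write_report <- function(metrics, path) {
  check <- function(x, key) {
    if (is.null(x)) return(invisible(TRUE))
    if (is.list(x)) {
      for (k in names(x)) check(x[[k]], k)
      return(invisible(TRUE))
    }
    if (!is.numeric(x) && !is.character(x) && !is.logical(x))
      stop_validation("non-serializable value for key '", key, "'")
    if (is.numeric(x) && any(!is.finite(x)))
      stop_validation("non-finite value for key '", key, "'")
    invisible(TRUE)
  }
  metrics <- unclass(metrics)
  if (length(metrics) && is.null(names(metrics)))
    stop_validation("metrics must be a named list")
  check(metrics, "<root>")
  if (!length(metrics)) metrics <- stats::setNames(list(), character(0))
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
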