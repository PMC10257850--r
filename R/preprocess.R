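# Standard scRNA-seq preprocessing ahead of the encoder: low-expression
# filtering, log1p normalization, highly-variable-gene selection, per-cell
# centering. Order is fixed: filter -> log1p -> HVG -> center.

#' Preprocessing configuration
#'
#' @param min_nonzero_frac_gene Genes detected (non-zero) in strictly fewer
#'   than this fraction of cells are dropped. Default 0.01.
#' @param min_nonzero_frac_cell Cells with strictly fewer than this fraction
#'   of the remaining genes detected are dropped. Default 0.01.
#' @param n_top_genes Number of highest-variance genes retained. Default 500.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(min_nonzero_frac_gene = 0.01,
                              min_nonzero_frac_cell = 0.01,
                              n_top_genes = 500) {
  if (min_nonzero_frac_gene < 0 || min_nonzero_frac_gene > 1 ||
      min_nonzero_frac_cell < 0 || min_nonzero_frac_cell > 1)
    stop_validation("non-zero fraction thresholds must lie in [0, 1]")
  if (n_top_genes < 1) stop_validation("n_top_genes must be >= 1")
  structure(list(min_nonzero_frac_gene = min_nonzero_frac_gene,
                 min_nonzero_frac_cell = min_nonzero_frac_cell,
                 n_top_genes = as.integer(n_top_genes)),
            class = "preprocess_config")
}

#' Remove rarely detected genes, then sparsely covered cells
#'
#' A gene is kept when its detection fraction (cells with a non-zero count)
#' is at least `min_nonzero_frac_gene`; on the remaining genes, a cell is
#' kept when its detected-gene fraction is at least `min_nonzero_frac_cell`.
#' One pass each, genes first.
#'
#' @param counts Cells-by-genes count matrix (dense or sparse, dimnames set).
#' @param cfg A [preprocess_config()].
#' @return Filtered count matrix.
#' @export
filter_low_expression <- function(counts, cfg = preprocess_config()) {
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop_validation("empty count matrix")
  nz_cells_per_gene <- Matrix::colSums(counts != 0)
  keep_g <- (nz_cells_per_gene / nrow(counts)) >= cfg$min_nonzero_frac_gene
  if (!any(keep_g))
    stop_validation("all ", ncol(counts), " genes removed by the ",
                    cfg$min_nonzero_frac_gene, " detection threshold")
  m <- counts[, keep_g, drop = FALSE]
  nz_genes_per_cell <- Matrix::rowSums(m != 0)
  keep_c <- (nz_genes_per_cell / ncol(m)) >= cfg$min_nonzero_frac_cell
  if (!any(keep_c))
    stop_validation("all ", nrow(counts), " cells removed by the ",
                    cfg$min_nonzero_frac_cell, " detection threshold (",
                    sum(keep_g), " genes had been retained)")
  m[keep_c, , drop = FALSE]
}

#' Natural-log normalization
#'
#' Elementwise `log(x + 1)`; zeros map to zero and shape is preserved.
#'
#' @param counts Non-negative matrix.
#' @return Dense numeric matrix.
#' @export
log_normalize <- function(counts) {
  m <- as_dense(counts)
  if (any(m < 0)) stop_validation("negative entries cannot be log-normalized")
  log1p(m)
}

#' Keep the highest-variance genes
#'
#' Per-gene variance (unbiased, n-1 denominator) computed on the matrix as
#' given — in the pipeline, after log-normalization. Ties at the selection
#' boundary are broken toward the smaller original column index; retained
#' genes keep their original order.
#'
#' @param m Numeric cells-by-genes matrix.
#' @param gene_ids Column identifiers (defaults to `colnames(m)`).
#' @param n_top Number of genes to keep; if more than available, all are kept.
#' @return List with `values` (subset matrix) and `gene_ids`.
#' @export
select_top_variance_genes <- function(m, gene_ids = colnames(m), n_top = 500) {
  if (n_top < 1) stop_validation("n_top must be >= 1")
  m <- as_dense(m)
  v <- matrixStats_colVars(m)
  k <- min(n_top, ncol(m))
  # order(-v, index) ranks by variance, tie-break on original index
  top <- sort(order(-v, seq_along(v))[seq_len(k)])
  list(values = m[, top, drop = FALSE], gene_ids = gene_ids[top])
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Center each cell at zero mean
#'
#' Subtracts every row's own mean; output row means are 0 within 1e-9.
#'
#' @param m Numeric matrix, cells in rows.
#' @return Centered matrix.
#' @export
center_per_cell <- function(m) {
  m <- as_dense(m)
  if (nrow(m) == 0 || ncol(m) == 0) stop_validation("empty matrix")
  sweep(m, 1, rowMeans(m))
}

#' Full preprocessing pipeline
#'
#' Applies, in order: low-expression filtering, log1p normalization,
#' top-variance gene selection, per-cell centering. Also returns the raw
#' counts restricted to the kept cells and genes — the reconstruction target
#' for the ZINB likelihood, which is defined on counts, not on the
#' transformed values.
#'
#' @param counts Cells-by-genes count matrix with dimnames.
#' @param cfg A [preprocess_config()].
#' @return A `processed_matrix` list: `values` (centered log counts for the
#'   encoder), `raw_counts` (kept cells x kept genes), `kept_cell_ids`,
#'   `kept_gene_ids`, `provenance` (ordered record of steps and parameters).
#' @export
preprocess_counts <- function(counts, cfg = preprocess_config()) {
  validate_counts(counts, rownames(counts), colnames(counts))
  filt <- filter_low_expression(counts, cfg)
  logm <- log_normalize(filt)
  sel <- select_top_variance_genes(logm, colnames(filt), cfg$n_top_genes)
  centered <- center_per_cell(sel$values)
  raw <- as_dense(filt[, match(sel$gene_ids, colnames(filt)), drop = FALSE])
  structure(list(
    values = centered,
    raw_counts = raw,
    kept_cell_ids = rownames(filt),
    kept_gene_ids = sel$gene_ids,
    provenance = list(
      filter = list(min_nonzero_frac_gene = cfg$min_nonzero_frac_gene,
                    min_nonzero_frac_cell = cfg$min_nonzero_frac_cell,
                    cells_kept = nrow(filt), genes_kept = ncol(filt),
                    cells_in = nrow(counts), genes_in = ncol(counts)),
      log_normalize = list(transform = "log1p"),
      select_top_variance_genes = list(n_top_genes = cfg$n_top_genes,
                                       genes_kept = length(sel$gene_ids)),
      center_per_cell = list(axis = "cell")
    )
  ), class = "processed_matrix")
}
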