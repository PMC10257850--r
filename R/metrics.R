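# Clustering evaluation: external agreement (ARI, NMI), internal quality
# (silhouette, Calinski-Harabasz), neighborhood preservation of an
# embedding, and run-to-run stability (coefficient of variation).

check_partition_pair <- function(a, b) {
  if (length(a) != length(b))
    stop_validation("label vectors differ in length")
  if (length(a) < 2) stop_validation("need at least 2 observations")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions on the scale
#' `[-1, 1]`; 1 means identical partitions up to label renaming.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  check_partition_pair(labels_a, labels_b)
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Normalized mutual information
#'
#' Mutual information of the two partitions normalized by the arithmetic
#' mean of their entropies; 1 for identical partitions, 0 when either
#' partition is a single cluster.
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  check_partition_pair(labels_a, labels_b)
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / outer(pa, pb)[pos]))
  mi / ((ha + hb) / 2)
}

#' Mean silhouette width
#'
#' Euclidean silhouette averaged over points; singleton clusters get width
#' 0 (the `cluster` package convention).
#'
#' @param Z Numeric matrix, points in rows.
#' @param labels One label per row, at least 2 distinct.
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(Z, labels) {
  Z <- as.matrix(Z)
  if (length(unique(labels)) < 2)
    stop_validation("silhouette needs at least 2 clusters")
  if (nrow(Z) < 3) stop_validation("need at least 3 points")
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(Z))
  mean(sil[, "sil_width"])
}

#' Calinski-Harabasz index (variance ratio criterion)
#'
#' `[tr(B) / (k - 1)] / [tr(W) / (n - k)]` with B and W the between- and
#' within-cluster scatter about the centroids. Zero within-cluster scatter
#' returns `Inf`.
#'
#' @inheritParams silhouette_score
#' @return Non-negative scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(Z, labels) {
  Z <- as.matrix(Z)
  f <- factor(labels)
  k <- nlevels(f); n <- nrow(Z)
  if (k < 2 || k >= n)
    stop_validation("need 2 <= k < n clusters")
  grand <- colMeans(Z)
  tr_b <- 0; tr_w <- 0
  for (lev in levels(f)) {
    zi <- Z[f == lev, , drop = FALSE]
    ci <- colMeans(zi)
    tr_b <- tr_b + nrow(zi) * sum((ci - grand)^2)
    tr_w <- tr_w + sum(sweep(zi, 2, ci)^2)
  }
  if (tr_w == 0) return(Inf)
  (tr_b / (k - 1)) / (tr_w / (n - k))
}

knn_sets <- function(X, K) {
  d2 <- sq_dists(X, X)
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(K)]))
}

#' K-nearest-neighbor preservation
#'
#' For each point, the fraction of its K nearest neighbors (Euclidean, self
#' excluded) in the original space that remain among its K nearest
#' neighbors in the embedding, averaged over points.
#'
#' @param X_orig Original-space matrix, n x d1.
#' @param X_embed Embedding, n x d2 (same row order).
#' @param K Neighborhood size, `1 <= K <= n - 1`.
#' @return Scalar in `[0, 1]`.
#' @export
knn_preservation <- function(X_orig, X_embed, K) {
  X_orig <- as.matrix(X_orig); X_embed <- as.matrix(X_embed)
  n <- nrow(X_orig)
  if (nrow(X_embed) != n) stop_validation("row counts differ")
  if (K < 1 || K > n - 1) stop_validation("K must lie in [1, n - 1]")
  a <- knn_sets(X_orig, K)
  b <- knn_sets(X_embed, K)
  mean(vapply(seq_len(n), function(i)
    length(intersect(a[i, ], b[i, ])) / K, numeric(1)))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean; used to
#' compare run-to-run stability of scores on different scales.
#'
#' @param scores Numeric vector, length >= 2, non-zero mean.
#' @return Non-negative scalar.
#' @export
coefficient_of_variation <- function(scores) {
  if (length(scores) < 2) stop_validation("need at least 2 scores")
  m <- mean(scores)
  if (m == 0) stop_validation("mean score is 0; CV undefined")
  sd(scores) / m
}

#' Evaluate a clustering result
#'
#' Bundles the external metrics (when truth labels are given) and internal
#' metrics on an embedding, plus K-NN preservation against an original
#' space when provided.
#'
#' @param Z Embedding matrix.
#' @param labels Predicted labels.
#' @param truth Optional reference labels.
#' @param X_orig Optional original-space matrix for K-NN preservation.
#' @param knn_grid Integer vector of K values.
#' @return Named list of metric values (a `metrics_report`).
#' @export
evaluate_clustering <- function(Z, labels, truth = NULL, X_orig = NULL,
                                knn_grid = integer(0)) {
  out <- list()
  if (!is.null(truth)) {
    out$ari <- ari(truth, labels)
    out$nmi <- nmi(truth, labels)
  }
  if (length(unique(labels)) >= 2 && nrow(as.matrix(Z)) > length(unique(labels))) {
    out$silhouette <- silhouette_score(Z, labels)
    out$calinski_harabasz <- calinski_harabasz(Z, labels)
  }
  if (!is.null(X_orig) && length(knn_grid)) {
    out$knn_preservation <- stats::setNames(
      lapply(knn_grid, function(K) knn_preservation(X_orig, Z, K)),
      paste0("K", knn_grid))
  }
  structure(out, class = "metrics_report")
}
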