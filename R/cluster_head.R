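# Deep-embedded-clustering head: Student-t soft assignments to learnable
# centers, a squared-and-renormalized target distribution, and the KL loss
# between them.

#' Student-t soft cluster assignments
#'
#' `q_ij = (1 + ||z_i - r_j||^2 / alpha)^(-(alpha+1)/2)`, normalized over
#' clusters j. With `alpha = 1` (the default throughout, since a validation
#' set for tuning it does not exist in unsupervised use) this is the Cauchy
#' kernel of t-SNE/DEC.
#'
#' @param Z Embedding, n x latent_dim.
#' @param R Cluster centers, k x latent_dim.
#' @param alpha Student-t degrees of freedom, > 0.
#' @return Row-stochastic n x k matrix Q.
#' @export
soft_assign <- function(Z, R, alpha = 1) {
  Z <- as.matrix(Z); R <- as.matrix(R)
  if (nrow(R) == 0) stop_validation("at least one center required")
  if (ncol(Z) != ncol(R)) stop_validation("Z and R dimension mismatch")
  if (alpha <= 0) stop_validation("alpha must be positive")
  u <- (1 + sq_dists(Z, R) / alpha)^(-(alpha + 1) / 2)
  u / rowSums(u)
}

#' Sharpened target distribution
#'
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with cluster frequency
#' `f_j = sum_i q_ij`. Squaring pushes each row toward its dominant cluster
#' while the frequency term counteracts collapse onto large clusters.
#'
#' @param Q Row-stochastic soft assignments.
#' @return Row-stochastic matrix P of the same shape.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- pmax(colSums(Q), 1e-12)
  w <- sweep(Q^2, 2, f, "/")
  w / rowSums(w)
}

#' Clustering KL loss
#'
#' `KL(P || Q)` summed over cells and clusters ([kl_discrete()]); during
#' training P is a fixed target and gradients flow only through Q.
#'
#' @param P Target distribution.
#' @param Q Soft assignments.
#' @return Non-negative scalar.
#' @export
clustering_loss <- function(P, Q) kl_discrete(P, Q)

# Gradient of KL(P||Q)/n (per-cell mean, Student-t kernel, fixed P) with
# respect to Z and R. Standard DEC result:
#   dL/dz_i =  ((alpha+1)/alpha) sum_j u_ij (q_ij - p_ij) (z_i - r_j) / n
#   dL/dr_j = -((alpha+1)/alpha) sum_i u_ij (q_ij - p_ij) (z_i - r_j) / n
# with u_ij = (1 + ||z_i - r_j||^2 / alpha)^-1.
cluster_kl_grad <- function(Z, R, P, alpha = 1) {
  n <- nrow(Z)
  u <- 1 / (1 + sq_dists(Z, R) / alpha)
  qnum <- u^((alpha + 1) / 2)
  Q <- qnum / rowSums(qnum)
  W <- ((alpha + 1) / alpha) * u * (P - Q) / n
  # sum_j W_ij (z_i - r_j) = rowSums(W) z_i - W R
  grad_Z <- rowSums(W) * Z - W %*% R
  grad_R <- colSums(W) * R - crossprod(W, Z)
  value <- kl_discrete(P, Q) / n
  list(value = value, Q = Q, grad_Z = grad_Z, grad_R = grad_R)
}

#' Initialize cluster centers by restarted k-means
#'
#' Runs `stats::kmeans` `n_restarts` times from distinct sub-seeds and keeps
#' the solution with the lowest total within-cluster sum of squares.
#'
#' @param Z Embedding matrix, n x latent_dim.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param n_restarts Number of independent initializations. Default 5.
#' @param seed Integer seed.
#' @return List with `centers` (k x latent_dim), `cluster` (integer labels),
#'   and `inertia` (best within-cluster sum of squares).
#' @export
init_centers <- function(Z, k, n_restarts = 5, seed = 1) {
  Z <- as.matrix(Z)
  if (nrow(Z) < k) stop_validation("need at least k = ", k, " points")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, paste0("kmeans", r)))
    fit <- suppressWarnings(
      kmeans(Z, centers = k, nstart = 1, iter.max = 200))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(centers = best$centers, cluster = best$cluster,
       inertia = best$tot.withinss)
}

#' Hard labels from soft assignments
#'
#' Argmax over clusters; ties resolve to the smallest cluster index.
#'
#' @param Q Row-stochastic soft-assignment matrix.
#' @return Integer vector of 1-based cluster labels, length `nrow(Q)`.
#' @export
hard_labels <- function(Q) {
  Q <- as.matrix(Q)
  max.col(Q, ties.method = "first")
}
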