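# Distribution-distance terms of the objective: kernel MMD between the
# aggregate posterior and the prior, the closed-form Gaussian KL against a
# standard-normal prior, and discrete KL between row-stochastic matrices.

#' Kernel configuration for the MMD penalty
#'
#' @param bandwidth Positive number, or `"median_heuristic"` to set the RBF
#'   bandwidth to the median pairwise Euclidean distance of the pooled
#'   sample (recomputed per call).
#' @param n_prior_samples Number of fresh standard-normal prior draws per
#'   batch; `NULL` means match the batch size.
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(bandwidth = "median_heuristic", n_prior_samples = NULL) {
  if (is.numeric(bandwidth) && bandwidth <= 0)
    stop_validation("bandwidth must be positive")
  structure(list(kind = "rbf", bandwidth = bandwidth,
                 n_prior_samples = n_prior_samples),
            class = "kernel_config")
}

# Median pairwise distance of the pooled sample, assembled from the three
# squared-distance blocks (cheaper than a fresh dist() on the pooled data).
bandwidth_from_blocks <- function(d2xx, d2yy, d2xy, cfg) {
  if (is.numeric(cfg$bandwidth)) return(cfg$bandwidth)
  pool <- c(d2xx[upper.tri(d2xx)], d2yy[upper.tri(d2yy)], as.vector(d2xy))
  pool <- pool[pool > 0]
  bw <- sqrt(median(pool))
  if (!is.finite(bw) || bw <= 0) bw <- 1
  bw
}

sq_dists <- function(X, Y) {
  # ||x_i - y_j||^2 via the expansion; clipped at 0 for rounding noise
  xx <- rowSums(X^2); yy <- rowSums(Y^2)
  d2 <- outer(xx, yy, "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

#' Biased squared maximum mean discrepancy
#'
#' V-statistic estimate with an RBF kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 bw^2))`:
#' `mean k(X, X) + mean k(Y, Y) - 2 mean k(X, Y)`. The biased estimator is
#' non-negative by construction, which the loss assembly relies on.
#'
#' @param X,Y Sample matrices with the same number of columns.
#' @param cfg A [kernel_config()].
#' @return Non-negative scalar.
#' @export
mmd_biased <- function(X, Y, cfg = kernel_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 1 || nrow(Y) < 1) stop_validation("empty sample")
  if (ncol(X) != ncol(Y)) stop_validation("dimension mismatch between samples")
  d2xx <- sq_dists(X, X); d2yy <- sq_dists(Y, Y); d2xy <- sq_dists(X, Y)
  bw <- bandwidth_from_blocks(d2xx, d2yy, d2xy, cfg)
  g <- 1 / (2 * bw^2)
  kxx <- mean(exp(-g * d2xx))
  kyy <- mean(exp(-g * d2yy))
  kxy <- mean(exp(-g * d2xy))
  max(kxx + kyy - 2 * kxy, 0)
}

# MMD value plus its gradient with respect to X (bandwidth treated as a
# constant, as is standard for the median heuristic).
mmd_biased_grad <- function(X, Y, cfg = kernel_config()) {
  n <- nrow(X); m <- nrow(Y)
  d2xx <- sq_dists(X, X); d2yy <- sq_dists(Y, Y); d2xy <- sq_dists(X, Y)
  bw <- bandwidth_from_blocks(d2xx, d2yy, d2xy, cfg)
  g <- 1 / (2 * bw^2)
  Kxx <- exp(-g * d2xx)
  Kxy <- exp(-g * d2xy)
  Kyy <- exp(-g * d2yy)
  value <- max(mean(Kxx) + mean(Kyy) - 2 * mean(Kxy), 0)
  # d mean(Kxx) / dX_i = (2 / n^2) sum_j Kxx_ij * 2g (x_j - x_i)
  #   (both orderings of the pair contribute)
  gx_xx <- (4 * g / n^2) * (Kxx %*% X - rowSums(Kxx) * X)
  # d (-2 mean(Kxy)) / dX_i = -(2 / (n m)) sum_j Kxy_ij * 2g (y_j - x_i)
  gx_xy <- -(4 * g / (n * m)) * (Kxy %*% Y - rowSums(Kxy) * X)
  list(value = value, grad_X = gx_xx + gx_xy)
}

#' Gaussian KL divergence to the standard-normal prior
#'
#' For a diagonal Gaussian `N(mean, exp(log_var))`:
#' `0.5 * sum(mean^2 + exp(log_var) - log_var - 1)`, which is zero exactly
#' when `mean = 0` and `log_var = 0`.
#'
#' @param mean,log_var Numeric vectors (or matrices, reduced as one vector).
#' @return Non-negative scalar.
#' @export
gaussian_kl_standard_prior <- function(mean, log_var) {
  if (any(!is.finite(mean)) || any(!is.finite(log_var)))
    stop_validation("non-finite inputs")
  0.5 * sum(mean^2 + exp(log_var) - log_var - 1)
}

#' Discrete KL divergence between row-stochastic matrices
#'
#' `sum_ij p_ij log(p_ij / q_ij)` with the conventions `0 log 0 = 0` and `q`
#' floored at `1e-12`.
#'
#' @param P,Q Matrices of the same shape, rows summing to 1 within 1e-6.
#' @return Non-negative scalar (total over all rows).
#' @export
kl_discrete <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop_validation("shape mismatch")
  if (any(abs(rowSums(P) - 1) > 1e-6) || any(abs(rowSums(Q) - 1) > 1e-6))
    stop_validation("rows must sum to 1")
  pos <- P > 0
  sum(P[pos] * (log(P[pos]) - log(pmax(Q[pos], 1e-12))))
}
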