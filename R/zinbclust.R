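#' Fit the deep embedded clustering model
#'
#' The main entry point: preprocesses a cells-by-genes count matrix
#' (optional), pretrains a variational autoencoder with a ZINB
#' reconstruction likelihood and a mutual-information-regularized latent
#' prior, then fine-tunes the embedding jointly with a Student-t clustering
#' head. Returns a fitted model object with the usual methods
#' (`print`, `summary`, `coef`, `fitted`, `predict`, `plot`).
#'
#' @param x Cells-by-genes matrix. Raw non-negative integer counts when
#'   `preprocess = TRUE` (the usual case); any real matrix when
#'   `preprocess = FALSE` (then pair it with
#'   `weights = loss_weights(recon_mode = "gaussian_mse")` unless the matrix
#'   itself is a valid ZINB target).
#' @param k Number of clusters (>= 2).
#' @param preprocess Logical; run [preprocess_counts()] first.
#' @param preprocess_cfg A [preprocess_config()].
#' @param hidden_dims,latent_dim,denoise_sigma Architecture, see
#'   [network_spec()].
#' @param weights A [loss_weights()].
#' @param pretrain_epochs,finetune_epochs Epochs per phase (defaults
#'   600/500).
#' @param lr_pretrain,lr_finetune Adam learning rates (defaults 1e-3/1e-4).
#' @param batch_size Minibatch size. Default 256.
#' @param alpha Student-t degrees of freedom of the clustering kernel.
#' @param kmeans_restarts Restarts for center initialization. Default 5.
#' @param seed Master seed; the whole fit is reproducible from it.
#' @param verbose Print progress.
#' @return An object of class `"zinbclust"`: `cluster` (1-based hard
#'   labels), `embedding` (n x latent_dim posterior means), `centers`,
#'   `Q`, `P`, `history` (per-epoch loss components), `net`, `weights`,
#'   `preprocess` (provenance or NULL), `cell_ids`, `call`, `seed`.
#' @examples
#' sim <- simulate_zinb_counts(zinb_sim_config(n_cells = 60, n_genes = 80,
#'                                             k_clusters = 2), seed = 1)
#' fit <- zinbclust(sim$counts, k = 2,
#'                  preprocess_cfg = preprocess_config(n_top_genes = 50),
#'                  hidden_dims = c(32, 16), pretrain_epochs = 5,
#'                  finetune_epochs = 5, seed = 1)
#' table(fit$cluster, sim$labels)
#' @export
zinbclust <- function(x, k, preprocess = TRUE,
                      preprocess_cfg = preprocess_config(),
                      hidden_dims = c(500, 256, 256), latent_dim = 10,
                      denoise_sigma = 0.1, weights = loss_weights(),
                      pretrain_epochs = 600, finetune_epochs = 500,
                      lr_pretrain = 1e-3, lr_finetune = 1e-4,
                      batch_size = 256, alpha = 1, kmeans_restarts = 5,
                      seed = 1, verbose = FALSE) {
  cl <- match.call()
  if (k < 2) stop_validation("k must be >= 2")
  if (preprocess) {
    data <- preprocess_counts(x, preprocess_cfg)
    prov <- data$provenance
    cell_ids <- data$kept_cell_ids
    transform <- list(kept_gene_ids = data$kept_gene_ids)
  } else {
    vals <- as_dense(x)
    data <- list(values = vals,
                 raw_counts = if (weights$recon_mode == "gaussian_mse") NULL
                              else vals)
    prov <- NULL
    cell_ids <- rownames(vals)
    transform <- NULL
  }
  spec <- network_spec(ncol(data$values), hidden_dims = hidden_dims,
                       latent_dim = latent_dim, denoise_sigma = denoise_sigma)
  net <- pretrain(data, spec, weights, epochs = pretrain_epochs,
                  lr = lr_pretrain, batch_size = batch_size,
                  seed = derive_seed(seed, "pretrain"), verbose = verbose)
  net <- finetune(net, data, k, weights, epochs = finetune_epochs,
                  lr = lr_finetune, batch_size = batch_size, alpha = alpha,
                  kmeans_restarts = kmeans_restarts,
                  seed = derive_seed(seed, "finetune"), verbose = verbose)
  Z <- encode(as.matrix(data$values), spec, net$params, mode = "eval")$z_mean
  rownames(Z) <- cell_ids
  structure(list(cluster = net$labels, embedding = Z,
                 centers = net$centers, Q = net$Q, P = net$P,
                 history = net$history, net = net, weights = weights,
                 k = as.integer(k), alpha = alpha,
                 preprocess = prov, transform = transform,
                 cell_ids = cell_ids, call = cl, seed = seed),
            class = "zinbclust")
}

#' @export
print.zinbclust <- function(x, ...) {
  cat("Deep embedded clustering fit (ZINB variational autoencoder)\n")
  cat(sprintf("  cells: %d, latent dim: %d, clusters: %d\n",
              nrow(x$embedding), ncol(x$embedding), x$k))
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  ft <- x$history[x$history$phase == "finetune", ]
  if (nrow(ft))
    cat(sprintf("  final loss: %.4f (clustering KL %.5f)\n",
                ft$total[nrow(ft)], ft$cluster_kl[nrow(ft)]))
  invisible(x)
}

#' @export
summary.zinbclust <- function(object, ...) {
  sizes <- tabulate(object$cluster, object$k)
  conf <- vapply(seq_len(nrow(object$Q)), function(i)
    object$Q[i, object$cluster[i]], numeric(1))
  internal <- list(
    silhouette = silhouette_score(object$embedding, object$cluster),
    calinski_harabasz = calinski_harabasz(object$embedding, object$cluster))
  out <- list(k = object$k, sizes = sizes, mean_confidence = mean(conf),
              internal = internal,
              history_tail = utils::tail(object$history, 3))
  class(out) <- "summary.zinbclust"
  out
}

#' @export
print.summary.zinbclust <- function(x, ...) {
  cat("Clusters:", x$k, "| sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("Mean assignment confidence: %.3f\n", x$mean_confidence))
  cat(sprintf("Silhouette: %.3f | Calinski-Harabasz: %.1f\n",
              x$internal$silhouette, x$internal$calinski_harabasz))
  cat("Last epochs:\n")
  print(x$history_tail, row.names = FALSE)
  invisible(x)
}

#' @export
coef.zinbclust <- function(object, ...) object$centers

#' @export
fitted.zinbclust <- function(object, ...) object$Q

#' Predict on new cells
#'
#' Applies the fitted preprocessing transform (kept-gene subset, log1p,
#' per-cell centering) when the model was fitted with preprocessing, then
#' encodes with the trained network.
#'
#' @param object A fitted `zinbclust` model.
#' @param newdata Cells-by-genes matrix (raw counts if the model
#'   preprocessed; same feature space as training otherwise).
#' @param type `"embedding"` (latent means), `"cluster"` (hard labels) or
#'   `"soft"` (Student-t soft assignments).
#' @param ... Unused.
#' @return Matrix or label vector according to `type`.
#' @export
predict.zinbclust <- function(object, newdata,
                              type = c("embedding", "cluster", "soft"), ...) {
  type <- match.arg(type)
  m <- as_dense(newdata)
  if (!is.null(object$transform)) {
    miss <- setdiff(object$transform$kept_gene_ids, colnames(m))
    if (length(miss))
      stop_validation(length(miss), " training genes absent from newdata")
    m <- center_per_cell(log_normalize(
      m[, object$transform$kept_gene_ids, drop = FALSE]))
  }
  Z <- encode(m, object$net$spec, object$net$params, mode = "eval")$z_mean
  if (type == "embedding") return(Z)
  Q <- soft_assign(Z, object$centers, object$alpha)
  if (type == "soft") Q else hard_labels(Q)
}

#' Plot a fitted model
#'
#' Scatter of the first two principal components of the latent embedding,
#' colored by cluster, with the projected centers marked.
#'
#' @param x A fitted `zinbclust` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.zinbclust <- function(x, ...) {
  pc <- stats::prcomp(x$embedding, rank. = 2)
  proj <- pc$x
  cent <- scale(x$centers, center = pc$center, scale = FALSE) %*% pc$rotation
  cols <- grDevices::hcl.colors(x$k, "Dark 3")
  graphics::plot(proj, col = cols[x$cluster], pch = 16, cex = 0.6,
                 xlab = "latent PC1", ylab = "latent PC2", ...)
  graphics::points(cent[, 1:2], pch = 4, cex = 2, lwd = 2)
  invisible(x)
}
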