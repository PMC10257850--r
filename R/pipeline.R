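# End-to-end pipeline and configuration layer. A run configuration is a
# plain named list (round-trips through YAML); run_pipeline() executes
# preprocess -> pretrain -> finetune -> post-hoc clustering -> evaluate and
# writes all artifacts to an output directory.

#' Cluster an embedding with a standard algorithm
#'
#' K-means (restarted, best within-cluster sum of squares kept) or
#' normalized-cut spectral clustering on the latent embedding.
#'
#' @param Z Embedding matrix, n x d.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param method `"kmeans"` or `"spectral"`.
#' @param seed Integer seed.
#' @param n_restarts K-means restarts. Default 5.
#' @return Integer vector of 1-based labels.
#' @export
cluster_embedding <- function(Z, k, method = c("kmeans", "spectral"),
                              seed = 1, n_restarts = 5) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  if (k < 2) stop_validation("k must be >= 2")
  if (nrow(Z) < k) stop_validation("need at least k points")
  if (method == "kmeans") {
    km <- init_centers(Z, k, n_restarts = n_restarts, seed = seed)
    km$cluster
  } else {
    set.seed(derive_seed(seed, "spectral"))
    as.integer(kernlab::specc(Z, centers = k))
  }
}

#' Default run configuration
#'
#' @param input Path to the count matrix (or an in-memory matrix).
#' @param format Input format, see [read_counts()].
#' @param k Number of clusters.
#' @param output_dir Artifact directory.
#' @param seed Master seed.
#' @param ... Overrides for any nested section (`preprocess`, `network`,
#'   `losses`, `train`, `cluster`, `evaluate`).
#' @return Nested configuration list.
#' @export
default_config <- function(input = NULL, format = "dense_csv", k = 2,
                           output_dir = "zinbclust_run", seed = 1, ...) {
  cfg <- list(
    input = input, format = format, k = k, output_dir = output_dir,
    seed = seed,
    preprocess = list(min_nonzero_frac_gene = 0.01,
                      min_nonzero_frac_cell = 0.01, n_top_genes = 500),
    network = list(hidden_dims = c(500, 256, 256), latent_dim = 10,
                   denoise_sigma = 0.1),
    losses = list(lambda_div = 1, alpha_mi = 0, gamma_cluster = 1,
                  c_recon = 0.5, recon_mode = "zinb_nll"),
    train = list(pretrain_epochs = 600, finetune_epochs = 500,
                 lr_pretrain = 1e-3, lr_finetune = 1e-4, batch_size = 256,
                 kmeans_restarts = 5, alpha = 1),
    cluster = list(posthoc = "kmeans"),
    evaluate = list(truth = NULL, knn_grid = integer(0)))
  modifyList(cfg, list(...))
}

#' Read / write a configuration file
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  modifyList(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg Configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("%s\t%s\tINFO\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
  writeLines(line, con)
}

#' Run the full pipeline
#'
#' Executes preprocessing, VAE pretraining, clustering fine-tuning, post-hoc
#' clustering of the embedding, and evaluation; writes `embedding.tsv`,
#' `labels.tsv`, `losses.csv`, `metrics.json`, `config.yaml` and `run.log`
#' to the output directory.
#'
#' @param cfg Configuration from [default_config()] or [read_config()].
#' @return The fitted `zinbclust` object, invisibly, with a `metrics`
#'   attribute.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(cfg$output_dir, "run.log"), "w")
  on.exit(close(logcon))
  stage <- "input"
  res <- tryCatch({
    counts <- if (is.matrix(cfg$input) || inherits(cfg$input, "Matrix"))
      cfg$input else read_counts(cfg$input, cfg$format)
    pipeline_log(logcon, stage, sprintf("loaded %d cells x %d genes",
                                        nrow(counts), ncol(counts)))
    stage <- "fit"
    fit <- zinbclust(
      counts, k = cfg$k,
      preprocess_cfg = preprocess_config(cfg$preprocess$min_nonzero_frac_gene,
                                         cfg$preprocess$min_nonzero_frac_cell,
                                         cfg$preprocess$n_top_genes),
      hidden_dims = cfg$network$hidden_dims,
      latent_dim = cfg$network$latent_dim,
      denoise_sigma = cfg$network$denoise_sigma,
      weights = loss_weights(cfg$losses$lambda_div, cfg$losses$alpha_mi,
                             cfg$losses$gamma_cluster, cfg$losses$c_recon,
                             cfg$losses$recon_mode),
      pretrain_epochs = cfg$train$pretrain_epochs,
      finetune_epochs = cfg$train$finetune_epochs,
      lr_pretrain = cfg$train$lr_pretrain,
      lr_finetune = cfg$train$lr_finetune,
      batch_size = cfg$train$batch_size, alpha = cfg$train$alpha,
      kmeans_restarts = cfg$train$kmeans_restarts, seed = cfg$seed)
    for (row in seq_len(nrow(fit$history)))
      if (row %% 100 == 0)
        pipeline_log(logcon, "fit",
                     sprintf("%s epoch %d total %.4f",
                             fit$history$phase[row], fit$history$epoch[row],
                             fit$history$total[row]))
    stage <- "posthoc_cluster"
    posthoc <- cluster_embedding(fit$embedding, cfg$k,
                                 method = cfg$cluster$posthoc,
                                 seed = derive_seed(cfg$seed, "posthoc"))
    stage <- "evaluate"
    truth <- if (!is.null(cfg$evaluate$truth)) {
      tl <- read_labels(cfg$evaluate$truth)
      unname(tl[fit$cell_ids])
    }
    metrics <- evaluate_clustering(fit$embedding, fit$cluster, truth = truth)
    metrics$posthoc_ari_vs_head <- ari(posthoc, fit$cluster)
    if (!is.null(truth)) metrics$posthoc_ari <- ari(truth, posthoc)
    stage <- "write"
    write_embedding(fit$embedding, fit$cell_ids,
                    file.path(cfg$output_dir, "embedding.tsv"))
    write_labels(fit$cluster, fit$cell_ids,
                 file.path(cfg$output_dir, "labels.tsv"))
    utils::write.csv(fit$history, file.path(cfg$output_dir, "losses.csv"),
                     row.names = FALSE)
    write_report(metrics, file.path(cfg$output_dir, "metrics.json"))
    cfg_out <- cfg; cfg_out$input <- if (is.character(cfg$input)) cfg$input else "<in-memory>"
    write_config(cfg_out, file.path(cfg$output_dir, "config.yaml"))
    pipeline_log(logcon, "done", "all artifacts written")
    attr(fit, "metrics") <- metrics
    attr(fit, "posthoc") <- posthoc
    fit
  }, error = function(e) {
    pipeline_log(logcon, stage, paste("ERROR:", conditionMessage(e)))
    stop(errorCondition(paste0("pipeline failed at stage '", stage, "': ",
                               conditionMessage(e)),
                        class = class(e)))
  })
  invisible(res)
}
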