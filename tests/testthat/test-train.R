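tiny_sim <- function(seed = 1, n = 120, g = 150) {
  sim <- simulate_zinb_counts(zinb_sim_config(n_cells = n, n_genes = g,
                                              k_clusters = 3), seed = seed)
  data <- preprocess_counts(sim$counts, preprocess_config(n_top_genes = 60))
  list(sim = sim, data = data)
}

test_that("loss weights validate their constraints", {
  expect_error(loss_weights(c_recon = 0), "positive")
  expect_error(loss_weights(alpha_mi = 1.5), "alpha_mi")
  w <- loss_weights(alpha_mi = 0, lambda_div = 1)
  expect_equal(w$alpha_mi + w$lambda_div - 1, 0)   # plain-VAE limit: no MMD
  expect_equal(1 - w$alpha_mi, 1)
})

test_that("reconstruction loss agrees with hand-computed ZINB pmfs", {
  x <- rbind(c(0, 2), c(1, 0))
  pi <- matrix(0.3, 2, 2); mu <- matrix(c(1, 2, 3, 4), 2); v <- c(1.5, 2.5)
  by_hand <- 0
  for (i in 1:2) for (j in 1:2) {
    nb <- exp(lgamma(x[i, j] + v[j]) - lgamma(x[i, j] + 1) - lgamma(v[j]) +
              v[j] * log(v[j] / (v[j] + mu[i, j])) +
              x[i, j] * log(mu[i, j] / (v[j] + mu[i, j])))
    p <- if (x[i, j] == 0) 0.3 + 0.7 * nb else 0.7 * nb
    by_hand <- by_hand - log(p)
  }
  expect_equal(reconstruction_loss(x, pi, mu, v, "zinb_nll"), by_hand / 4,
               tolerance = 1e-10)
  # mean_mse vanishes at the ZINB mean and both modes are non-negative
  expect_equal(reconstruction_loss((1 - pi) * mu, pi, mu, v, "mean_mse"), 0)
  expect_gte(reconstruction_loss(x, pi, mu, v, "zinb_nll"), 0)
  expect_error(reconstruction_loss(x + 0.5, pi, mu, v, "zinb_nll"), "integer")
})

test_that("analytic gradients of the full objective match finite differences", {
  su <- gradcheck_setup()
  err <- gradcheck_max_rel_error(su, all_leaf_paths(), n_coords = 4)
  expect_lt(err, 1e-4)
})

test_that("loss breakdown recombines into the total and drops terms as weights vanish", {
  su <- gradcheck_setup()
  w <- su$weights
  bd <- gradcheck_loss(su, su$params)$breakdown
  expect_equal(bd$total,
               bd$recon / (2 * w$c_recon) + (1 - w$alpha_mi) * bd$kl_per_sample +
                 (w$alpha_mi + w$lambda_div - 1) * bd$divergence +
                 w$gamma_cluster * bd$cluster_kl,
               tolerance = 1e-10)
  # without a cluster state and with plain-VAE weights the extras vanish
  bd0 <- loss_breakdown(su$x, su$ctar, su$spec, su$params, loss_weights())
  expect_identical(bd0$cluster_kl, 0)
  expect_identical(bd0$divergence, 0)
  expect_equal(bd0$total, bd0$recon / (2 * 0.5) + bd0$kl_per_sample,
               tolerance = 1e-10)
})

test_that("pretraining reduces the loss and is bit-reproducible", {
  ts <- tiny_sim()
  net1 <- do.call(pretrain, c(list(ts$data,
                                   spec = network_spec(60, c(32, 16), 4),
                                   epochs = 30, seed = 7)))
  expect_lt(net1$history$total[30], net1$history$total[1])
  net2 <- pretrain(ts$data, network_spec(60, c(32, 16), 4),
                   epochs = 30, seed = 7)
  expect_identical(net1$history$total, net2$history$total)
  expect_identical(net1$params$enc[[1]]$W, net2$params$enc[[1]]$W)
  emb <- encode(ts$data$values, net1$spec, net1$params)$z_mean
  expect_equal(ncol(emb), 4L)
})

test_that("the loss decreases across pretraining for most seeds", {
  wins <- 0
  for (seed in 1:5) {
    ts <- tiny_sim(seed)
    net <- pretrain(ts$data, network_spec(60, c(32, 16), 4),
                    epochs = 25, seed = seed)
    wins <- wins + (net$history$total[25] < net$history$total[1])
  }
  expect_gte(wins, 4)
})

test_that("fine-tuning attaches a clustering head and returns labels", {
  ts <- tiny_sim()
  spec <- network_spec(60, c(32, 16), 4)
  net <- pretrain(ts$data, spec, epochs = 40, seed = 3)
  ft <- finetune(net, ts$data, k = 3, epochs = 30, seed = 3)
  expect_length(ft$labels, 120L)
  expect_equal(sort(unique(ft$labels)), 1:3)
  expect_equal(dim(ft$centers), c(3L, 4L))
  fth <- ft$history[ft$history$phase == "finetune", ]
  expect_lte(mean(utils::tail(fth$cluster_kl, 5)),
             mean(utils::head(fth$cluster_kl, 5)) + 1e-3)
  # the recombination identity holds at every logged epoch
  w <- net$weights
  with(ft$history, expect_lt(max(abs(
    total - (recon / (2 * w$c_recon) + (1 - w$alpha_mi) * kl_per_sample +
             (w$alpha_mi + w$lambda_div - 1) * divergence +
             w$gamma_cluster * cluster_kl))), 1e-10))
  expect_true(all(is.finite(as.matrix(ft$history[, -(1:2)]))))
})

test_that("fine-tuning recovers planted clusters on a separated simulation", {
  ts <- tiny_sim(seed = 2, n = 150, g = 200)
  fit <- zinbclust(ts$sim$counts, k = 3,
                   preprocess_cfg = preprocess_config(n_top_genes = 80),
                   hidden_dims = c(32, 16), latent_dim = 4,
                   pretrain_epochs = 400, finetune_epochs = 150, seed = 4)
  expect_gte(ari(ts$sim$labels, fit$cluster), 0.9)
})

test_that("the fitted model object supports the standard methods", {
  ts <- tiny_sim()
  fit <- zinbclust(ts$sim$counts, k = 3,
                   preprocess_cfg = preprocess_config(n_top_genes = 60),
                   hidden_dims = c(32, 16), latent_dim = 4,
                   pretrain_epochs = 15, finetune_epochs = 10, seed = 1)
  expect_s3_class(fit, "zinbclust")
  expect_output(print(fit), "clusters: 3")
  s <- summary(fit)
  expect_s3_class(s, "summary.zinbclust")
  expect_equal(sum(s$sizes), 120)
  expect_equal(dim(coef(fit)), c(3L, 4L))
  expect_equal(dim(fitted(fit)), c(120L, 3L))
  # predict on the training counts reproduces the stored quantities
  emb <- predict(fit, ts$sim$counts, type = "embedding")
  expect_equal(unname(emb), unname(fit$embedding), tolerance = 1e-12)
  cl <- predict(fit, ts$sim$counts, type = "cluster")
  expect_equal(cl, fit$cluster)
  soft <- predict(fit, ts$sim$counts, type = "soft")
  expect_lt(max(abs(rowSums(soft) - 1)), 1e-9)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
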