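# Finite-difference checking of the analytic gradients of the composite
# objective. Builds a small batch problem with every loss term active and
# compares analytic gradients to central differences on random parameter
# coordinates.

gradcheck_setup <- function(n = 16, d = 50, latent = 4, seed = 42) {
  set.seed(seed)
  spec <- network_spec(d, hidden_dims = c(20, 12), latent_dim = latent)
  params <- init_network(spec, seed = seed + 1)
  x <- matrix(rnorm(n * d), n)
  ctar <- matrix(rpois(n * d, 3), n)
  noise <- list(input = matrix(rnorm(n * d, sd = 0.1), n),
                eps = matrix(rnorm(n * latent), n),
                prior = matrix(rnorm(n * latent), n))
  weights <- loss_weights(lambda_div = 1.1, alpha_mi = 0.9,
                          gamma_cluster = 1.3, c_recon = 0.5)
  kc <- kernel_config(bandwidth = 1.5)   # fixed so the loss is smooth
  z0 <- encode(x, spec, params)$z_mean
  km <- init_centers(z0, 3, seed = 1)
  params$centers <- km$centers
  P <- target_distribution(soft_assign(z0, km$centers))
  list(spec = spec, params = params, x = x, ctar = ctar, noise = noise,
       weights = weights, kc = kc, P = P)
}

gradcheck_loss <- function(su, params) {
  cs <- list(P = su$P, centers = params$centers, alpha = 1)
  zinbclust:::forward_backward(params, su$x, su$ctar, su$spec, su$weights,
                               su$noise, cs, su$kc)
}

get_leaf <- function(p, path) { for (k in path) p <- p[[k]]; p }
set_leaf <- function(p, path, val) {
  if (length(path) == 1) { p[[path[[1]]]] <- val; return(p) }
  p[[path[[1]]]] <- set_leaf(p[[path[[1]]]], path[-1], val)
  p
}

# max relative FD error over n_coords random coordinates of each leaf
gradcheck_max_rel_error <- function(su, leaf_paths, n_coords = 5, h = 1e-5) {
  out <- gradcheck_loss(su, su$params)
  worst <- 0
  for (pt in leaf_paths) {
    mat <- get_leaf(su$params, pt)
    g <- get_leaf(out$grads, pt)
    for (i in sample(length(mat), min(n_coords, length(mat)))) {
      up <- mat; up[i] <- up[i] + h
      dn <- mat; dn[i] <- dn[i] - h
      lp <- gradcheck_loss(su, set_leaf(su$params, pt, up))$breakdown$total
      lm <- gradcheck_loss(su, set_leaf(su$params, pt, dn))$breakdown$total
      fd <- (lp - lm) / (2 * h)
      rel <- abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-6)
      worst <- max(worst, rel)
    }
  }
  worst
}

all_leaf_paths <- function() {
  list(list("enc", 1L, "W"), list("enc", 2L, "b"), list("z_mean", "W"),
       list("z_log_var", "W"), list("z_log_var", "b"), list("dec", 1L, "W"),
       list("dec", 2L, "b"), list("out_mu", "W"), list("out_pi", "W"),
       list("out_pi", "b"), list("log_theta"), list("centers"))
}
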