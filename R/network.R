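# Encoder/decoder multilayer perceptrons. The encoder maps the processed
# expression matrix to a diagonal-Gaussian posterior (mean and log-variance
# heads) in the latent space; the decoder mirrors the hidden stack and emits
# the three ZINB heads: mean mu (exp link), dropout pi (logit link) and a
# free per-gene dispersion v (softplus link, shared across cells).
#
# Forward passes cache pre-activations so the training loop can run the
# hand-derived backward pass; everything is plain matrix algebra.

LOGVAR_CLAMP <- c(-10, 10)   # keeps exp(log_var) and the KL term bounded
MU_EXP_CLAMP <- c(-12, 14)   # mu in (6e-6, 1.2e6)

#' Network architecture specification
#'
#' The default realizes the `d - 500 - 256 - 256 - 10` stack (and its mirror
#' image in the decoder) with ReLU activations.
#'
#' @param input_dim Number of input features `d` (genes after selection).
#' @param hidden_dims Encoder hidden-layer widths; the decoder uses them
#'   reversed. Default `c(500, 256, 256)`.
#' @param latent_dim Latent dimension. Default 10.
#' @param denoise_sigma Standard deviation of the Gaussian input noise used
#'   in train mode (denoising autoencoder). Default 0.1.
#' @return A `network_spec` list.
#' @export
network_spec <- function(input_dim, hidden_dims = c(500, 256, 256),
                         latent_dim = 10, denoise_sigma = 0.1) {
  if (input_dim < 1 || latent_dim < 1 || any(hidden_dims < 1))
    stop_validation("all layer sizes must be >= 1")
  if (denoise_sigma < 0) stop_validation("denoise_sigma must be >= 0")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim),
                 activation = "relu",
                 denoise_sigma = denoise_sigma),
            class = "network_spec")
}

new_linear <- function(fan_in, fan_out, gain = 2) {
  # He-style scaling for the ReLU stack, Xavier-like when gain = 1
  sd <- sqrt(gain / fan_in)
  list(W = matrix(rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out),
       b = rep(0, fan_out))
}

#' Initialize network parameters
#'
#' Reproducible given the seed; weights use fan-in-scaled Gaussian draws,
#' biases start at zero, the per-gene dispersion starts at `softplus^-1(1)`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return Nested list of parameter matrices (`enc`, `z_mean`, `z_log_var`,
#'   `dec`, `out_mu`, `out_pi`, `log_theta`).
#' @export
init_network <- function(spec, seed = 1) {
  set.seed(seed)
  dims_enc <- c(spec$input_dim, spec$hidden_dims)
  enc <- lapply(seq_along(spec$hidden_dims), function(l)
    new_linear(dims_enc[l], dims_enc[l + 1]))
  last <- spec$hidden_dims[length(spec$hidden_dims)]
  dims_dec <- c(spec$latent_dim, rev(spec$hidden_dims))
  dec <- lapply(seq_along(spec$hidden_dims), function(l)
    new_linear(dims_dec[l], dims_dec[l + 1]))
  last_dec <- dims_dec[length(dims_dec)]
  list(enc = enc,
       z_mean = new_linear(last, spec$latent_dim, gain = 1),
       z_log_var = new_linear(last, spec$latent_dim, gain = 1),
       dec = dec,
       out_mu = new_linear(last_dec, spec$input_dim, gain = 1),
       out_pi = new_linear(last_dec, spec$input_dim, gain = 1),
       log_theta = rep(log(exp(1) - 1), spec$input_dim))
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

mlp_forward <- function(x, layers) {
  A <- vector("list", length(layers))
  H <- vector("list", length(layers))
  h <- x
  for (l in seq_along(layers)) {
    A[[l]] <- add_bias(h %*% layers[[l]]$W, layers[[l]]$b)
    h <- pmax(A[[l]], 0)
    H[[l]] <- h
  }
  list(out = h, A = A, H = H)
}

# Backward through a ReLU MLP. d_out is the gradient at the stack output;
# returns gradient lists per layer and the gradient at the stack input.
mlp_backward <- function(x, layers, fw, d_out) {
  L <- length(layers)
  grads <- vector("list", L)
  d <- d_out
  for (l in rev(seq_len(L))) {
    d <- d * (fw$A[[l]] > 0)
    h_prev <- if (l == 1) x else fw$H[[l - 1]]
    grads[[l]] <- list(W = crossprod(h_prev, d), b = colSums(d))
    d <- tcrossprod(d, layers[[l]]$W)
  }
  list(grads = grads, d_input = d)
}

linear_forward <- function(h, layer) add_bias(h %*% layer$W, layer$b)

#' Encode cells into the latent space
#'
#' Two parallel linear heads on the last hidden layer give the posterior
#' mean and log-variance. In train mode, Gaussian noise of scale
#' `denoise_sigma` is added to the input (denoising) and `z_sample` is the
#' reparameterized draw `z_mean + exp(log_var / 2) * eps`; in eval mode the
#' pass is noise-free and `z_sample = z_mean`.
#'
#' @param x Numeric matrix, cells in rows, `spec$input_dim` columns.
#' @param spec A [network_spec()].
#' @param params Parameters from [init_network()].
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @return List with `z_mean`, `z_log_var`, `z_sample` (n x latent_dim) and
#'   an internal `cache` used by the training loop.
#' @export
encode <- function(x, spec, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (ncol(x) != spec$input_dim)
    stop_validation("x has ", ncol(x), " columns; expected ", spec$input_dim)
  xn <- x
  if (mode == "train" && spec$denoise_sigma > 0)
    xn <- x + matrix(rnorm(length(x), sd = spec$denoise_sigma), nrow(x))
  fw <- mlp_forward(xn, params$enc)
  z_mean <- linear_forward(fw$out, params$z_mean)
  lv_raw <- linear_forward(fw$out, params$z_log_var)
  z_log_var <- pmin(pmax(lv_raw, LOGVAR_CLAMP[1]), LOGVAR_CLAMP[2])
  if (mode == "train") {
    eps <- matrix(rnorm(length(z_mean)), nrow(z_mean))
    z_sample <- z_mean + exp(z_log_var / 2) * eps
  } else {
    eps <- NULL
    z_sample <- z_mean
  }
  list(z_mean = z_mean, z_log_var = z_log_var, z_sample = z_sample,
       cache = list(xn = xn, fw = fw, lv_raw = lv_raw, eps = eps))
}

#' Decode latent points into ZINB parameters
#'
#' @param z Numeric matrix, `spec$latent_dim` columns.
#' @inheritParams encode
#' @return List with `pi` (in `[0,1]`), `mu` (> 0), both n x d, and `v`
#'   (positive per-gene dispersion vector of length d), plus an internal
#'   `cache`.
#' @export
decode <- function(z, spec, params) {
  z <- as.matrix(z)
  if (ncol(z) != spec$latent_dim)
    stop_validation("z has ", ncol(z), " columns; expected ", spec$latent_dim)
  fw <- mlp_forward(z, params$dec)
  a_mu <- linear_forward(fw$out, params$out_mu)
  a_mu_c <- pmin(pmax(a_mu, MU_EXP_CLAMP[1]), MU_EXP_CLAMP[2])
  mu <- exp(a_mu_c)
  a_pi <- linear_forward(fw$out, params$out_pi)
  pi <- 1 / (1 + exp(-a_pi))
  v <- log1p(exp(params$log_theta))          # softplus, length d
  v <- pmax(v, 1e-6)
  list(pi = pi, mu = mu, v = v,
       cache = list(fw = fw, a_mu = a_mu, a_pi = a_pi))
}
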