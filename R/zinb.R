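# Zero-inflated negative binomial reconstruction model. The NB is
# parameterized by its mean mu and dispersion v (variance mu + mu^2/v, so
# v -> Inf recovers the Poisson); the ZINB mixes a point mass at zero with
# weight pi into the NB.

#' Negative binomial log pmf (mean/dispersion parameterization)
#'
#' `log NB(x | mu, v) = lgamma(x + v) - lgamma(x + 1) - lgamma(v)
#'  + v log(v / (v + mu)) + x log(mu / (v + mu))`.
#'
#' @param x Non-negative integer counts (vector or matrix).
#' @param mu Mean, > 0 (recycled against `x`).
#' @param v Dispersion, > 0.
#' @return Log probability mass, same shape as `x`.
#' @export
nb_log_pmf <- function(x, mu, v) {
  if (any(x < 0) || !all(is_wholenumber(x)))
    stop_validation("x must be non-negative integers")
  if (any(mu <= 0) || any(v <= 0))
    stop_validation("mu and v must be positive")
  out <- dnbinom(as.vector(round(x)), size = v, mu = mu, log = TRUE)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Zero-inflated negative binomial log pmf
#'
#' `log[ pi 1{x = 0} + (1 - pi) NB(x | mu, v) ]`, evaluated stably in log
#' space for `x = 0`.
#'
#' @inheritParams nb_log_pmf
#' @param pi Dropout (zero-inflation) probability in `[0, 1]`.
#' @param floor Probabilities are floored here before the log, so the value
#'   is finite even at `pi = 1, x > 0`.
#' @return Log probability mass, same shape as `x`.
#' @export
zinb_log_pmf <- function(x, pi, mu, v, floor = 1e-12) {
  if (any(pi < 0) || any(pi > 1)) stop_validation("pi must lie in [0, 1]")
  nb <- nb_log_pmf(x, mu, v)
  # broadcast pi to the shape of x
  pi_full <- x * 0 + pi
  out <- log(pmax(1 - pi_full, floor)) + nb
  zero <- x == 0
  if (any(zero)) {
    # log(pi + (1 - pi) NB0) via log-sum-exp; pi = 0 reduces to the NB
    # branch exactly (a = -Inf contributes nothing)
    a <- log(pi_full[zero])
    b <- log(pmax(1 - pi_full[zero], floor)) + nb[zero]
    m <- pmax(a, b)
    out[zero] <- m + log(exp(a - m) + exp(b - m))
  }
  pmax(out, log(floor))
}

#' Mean of the ZINB mixture
#'
#' @inheritParams zinb_log_pmf
#' @return `(1 - pi) * mu`, elementwise.
#' @export
zinb_mean <- function(pi, mu) {
  if (any(pi < 0) || any(pi > 1)) stop_validation("pi must lie in [0, 1]")
  (1 - pi) * mu
}

#' Draw from the ZINB distribution
#'
#' A Bernoulli(`pi`) dropout mask zeroes NB(mu, v) draws.
#'
#' @param n Number of draws.
#' @inheritParams zinb_log_pmf
#' @return Integer vector of length `n`.
#' @export
rzinb <- function(n, pi, mu, v) {
  drop <- rbinom(n, 1, pi)
  x <- rnbinom(n, size = v, mu = mu)
  x * (1 - drop)
}
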