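#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans rnorm runif rbinom rnbinom var dist median dnbinom
#'   predict quantile sd
#' @importFrom utils read.table write.table modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib zinbclust, .registration = TRUE
NULL

# Consistent error signalling: validation errors get a dedicated class so
# callers (and the CLI) can map them to exit codes.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("zinbclust_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("zinbclust_io_error", "error")))
}

#' Derive reproducible stage seeds from a master seed
#'
#' Every stochastic stage of the pipeline (simulation, parameter
#' initialization, minibatch shuffling, prior draws, k-means restarts) draws
#' its own seed deterministically from one master seed, so a whole run is
#' reproducible from a single integer.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  # small deterministic hash of the stage string mixed with the seed
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

is_wholenumber <- function(x, tol = 1e-8) {
  abs(x - round(x)) < tol
}
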