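# Synthetic benchmark generators. Two fixtures: (1) a 2D six-cluster layout
# with uniform outliers, lifted to nine dimensions by a fixed polynomial
# map and max-abs scaled — exercises structure preservation; (2) ZINB count
# matrices with planted clusters and marker genes — exercises the full
# count pipeline.

#' Configuration of the 2D six-cluster benchmark
#'
#' One large Gaussian cluster on the left, five small mutually close
#' Gaussian clusters arranged on a pentagon on the right, and uniform
#' outliers in a box surrounding everything. The stated counts (1000 +
#' 5 x 200 + 200 outliers = 2200 points) are the defaults; the exact
#' geometry (centers, spreads, box) is not dictated by the counts and is
#' chosen here so the small clusters are close yet resolvable.
#'
#' @param n_large Points in the large cluster. Default 1000.
#' @param n_small_each Points per small cluster. Default 200.
#' @param n_small_clusters Number of small clusters. Default 5.
#' @param n_outliers Uniform outliers. Default 200.
#' @param large_center,large_spread Center and s.d. of the large cluster.
#' @param small_group_center Center of the pentagon of small clusters.
#' @param small_radius Pentagon circumradius.
#' @param small_spread Per-axis s.d. of each small cluster.
#' @param outlier_box `c(xmin, xmax, ymin, ymax)` for the uniform outliers.
#' @return A `synthetic_2d_config` list.
#' @export
synthetic_2d_config <- function(n_large = 1000, n_small_each = 200,
                                n_small_clusters = 5, n_outliers = 200,
                                large_center = c(-5, 0), large_spread = 0.8,
                                small_group_center = c(5, 0),
                                small_radius = 1.8, small_spread = 0.25,
                                outlier_box = c(-8, 8, -5, 5)) {
  if (any(c(n_large, n_small_each, n_small_clusters, n_outliers) < 0))
    stop_validation("counts must be >= 0")
  structure(as.list(environment()), class = "synthetic_2d_config")
}

#' Generate the 2D clustered benchmark
#'
#' @param cfg A [synthetic_2d_config()].
#' @param seed Integer seed; the point set is deterministic given it.
#' @return List with `points` (n x 2) and `labels` (integer; 0 for the large
#'   cluster, 1..5 for the small clusters, -1 for outliers).
#' @export
generate_2d <- function(cfg = synthetic_2d_config(), seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 2)
  labels <- integer(0)
  if (cfg$n_large > 0) {
    pts <- rbind(pts, cbind(rnorm(cfg$n_large, cfg$large_center[1], cfg$large_spread),
                            rnorm(cfg$n_large, cfg$large_center[2], cfg$large_spread)))
    labels <- c(labels, rep(0L, cfg$n_large))
  }
  ang <- 2 * pi * (seq_len(cfg$n_small_clusters) - 1) / cfg$n_small_clusters
  centers <- cbind(cfg$small_group_center[1] + cfg$small_radius * cos(ang),
                   cfg$small_group_center[2] + cfg$small_radius * sin(ang))
  for (j in seq_len(cfg$n_small_clusters)) {
    pts <- rbind(pts, cbind(rnorm(cfg$n_small_each, centers[j, 1], cfg$small_spread),
                            rnorm(cfg$n_small_each, centers[j, 2], cfg$small_spread)))
    labels <- c(labels, rep(as.integer(j), cfg$n_small_each))
  }
  if (cfg$n_outliers > 0) {
    pts <- rbind(pts, cbind(runif(cfg$n_outliers, cfg$outlier_box[1], cfg$outlier_box[2]),
                            runif(cfg$n_outliers, cfg$outlier_box[3], cfg$outlier_box[4])))
    labels <- c(labels, rep(-1L, cfg$n_outliers))
  }
  colnames(pts) <- c("x", "y")
  list(points = pts, labels = labels)
}

#' Lift 2D points to nine dimensions
#'
#' Applies, per point `(x, y)`, the monomial map
#' `(x + y, x - y, xy, x^2, y^2, x^2 y, x y^2, x^3, y^3)` in that order.
#'
#' @param points Numeric matrix with 2 columns.
#' @return n x 9 matrix.
#' @export
embed_9d <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop_validation("points must have exactly 2 columns")
  x <- points[, 1]; y <- points[, 2]
  out <- cbind(x + y, x - y, x * y, x^2, y^2, x^2 * y, x * y^2, x^3, y^3)
  colnames(out) <- c("x+y", "x-y", "xy", "x2", "y2", "x2y", "xy2", "x3", "y3")
  out
}

#' Column-wise max-abs scaling
#'
#' Divides each column by its maximum absolute value; all-zero columns are
#' left unchanged. Signs are preserved and the transform is idempotent.
#'
#' @param X Numeric matrix.
#' @return Matrix of the same shape with column-wise max abs 1 (or 0).
#' @export
scale_max_abs <- function(X) {
  X <- as.matrix(X)
  m <- apply(abs(X), 2, max)
  m[m == 0] <- 1
  sweep(X, 2, m, "/")
}

#' Configuration of the planted-cluster ZINB simulation
#'
#' Each cluster has a distinct set of marker genes whose NB mean is
#' up-scaled by `effect_size`; every entry is then drawn from
#' `ZINB(pi_g, mu_{cluster,g}, v)` with a per-gene dropout rate drawn
#' uniformly from `pi_range`.
#'
#' @param n_cells,n_genes,k_clusters Matrix size and number of clusters.
#' @param pi_range Per-gene dropout probability range, inside `[0, 1)`.
#' @param mu_scale Median of the log-normal baseline gene means.
#' @param v NB dispersion (shared).
#' @param effect_size Fold change of cluster marker genes. Default 8.
#' @param marker_frac Fraction of genes that are markers of each cluster.
#' @return A `zinb_sim_config` list.
#' @export
zinb_sim_config <- function(n_cells = 300, n_genes = 1000, k_clusters = 3,
                            pi_range = c(0.1, 0.4), mu_scale = 1, v = 2,
                            effect_size = 8, marker_frac = 0.1) {
  if (any(pi_range < 0) || any(pi_range >= 1))
    stop_validation("pi_range must lie inside [0, 1)")
  if (k_clusters < 1 || n_cells < k_clusters)
    stop_validation("need n_cells >= k_clusters >= 1")
  structure(as.list(environment()), class = "zinb_sim_config")
}

#' Simulate a count matrix with planted clusters
#'
#' @param cfg A [zinb_sim_config()].
#' @param seed Integer seed.
#' @return List with `counts` (cells x genes integer matrix with ids) and
#'   `labels` (integer cluster of each cell, 1..k).
#' @export
simulate_zinb_counts <- function(cfg = zinb_sim_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n_cells; g <- cfg$n_genes; k <- cfg$k_clusters
  labels <- sort(rep_len(seq_len(k), n))
  base_mu <- cfg$mu_scale * exp(rnorm(g, 0, 0.5))
  pi_g <- runif(g, cfg$pi_range[1], cfg$pi_range[2])
  n_mark <- max(1, round(cfg$marker_frac * g))
  marker_sets <- split(seq_len(min(k * n_mark, g)),
                       rep_len(seq_len(k), min(k * n_mark, g)))
  mu_clust <- matrix(base_mu, k, g, byrow = TRUE)
  for (j in seq_len(k))
    mu_clust[j, marker_sets[[j]]] <- mu_clust[j, marker_sets[[j]]] * cfg$effect_size
  counts <- matrix(0L, n, g)
  for (i in seq_len(n)) {
    mu_i <- mu_clust[labels[i], ]
    counts[i, ] <- as.integer(rzinb(g, pi_g, mu_i, cfg$v))
  }
  dimnames(counts) <- list(paste0("cell", seq_len(n)), paste0("gene", seq_len(g)))
  list(counts = counts, labels = labels)
}
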