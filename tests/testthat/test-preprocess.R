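test_that("genes below the detection threshold are removed, then cells", {
  set.seed(7)
  m <- matrix(rpois(200 * 10, 3) + 1L, 200, 10)   # everything detected
  dimnames(m) <- list(paste0("c", 1:200), paste0("g", 1:10))
  m[, 3] <- 0L                                    # undetected gene
  out <- filter_low_expression(m, preprocess_config())
  expect_equal(colnames(out), paste0("g", c(1, 2, 4:10)))
  expect_equal(nrow(out), 200L)
  # fully detected matrix is unchanged
  m2 <- m[, -3]
  expect_equal(filter_low_expression(m2, preprocess_config()), m2)
})

test_that("detection fractions follow direct enumeration", {
  set.seed(21)
  m <- matrix(rpois(100 * 10, 2) + 1L, 100, 10)
  dimnames(m) <- list(paste0("c", 1:100), paste0("g", 1:10))
  dead <- c(2, 5, 9)
  m[, dead] <- 0L
  out <- filter_low_expression(m, preprocess_config())
  expect_equal(ncol(out), 7L)
  expect_false(any(paste0("g", dead) %in% colnames(out)))
})

test_that("filtering is idempotent and empty results raise errors", {
  set.seed(3)
  m <- matrix(rbinom(50 * 20, 10, 0.15), 50, 20)
  dimnames(m) <- list(paste0("c", 1:50), paste0("g", 1:20))
  cfg <- preprocess_config(0.1, 0.1)
  f1 <- filter_low_expression(m, cfg)
  expect_equal(filter_low_expression(f1, cfg), f1)
  z <- m; z[] <- 0L
  expect_error(filter_low_expression(z, cfg), "genes removed")
})

test_that("log normalization is natural log1p", {
  expect_equal(log_normalize(matrix(0)), matrix(0))
  expect_equal(log_normalize(matrix(exp(1) - 1)), matrix(1))
  expect_equal(log_normalize(matrix(1))[1], log(2), tolerance = 1e-12)
  expect_error(log_normalize(matrix(-1)), "negative")
})

test_that("top-variance selection matches brute-force ranking", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(40 * 30, sd = runif(30, 0.1, 3)[col(matrix(0, 40, 30))]),
                40, 30)
    colnames(m) <- paste0("g", 1:30)
    sel <- select_top_variance_genes(m, n_top = 12)
    v <- apply(m, 2, var)
    expect_setequal(sel$gene_ids,
                    colnames(m)[order(-v)[1:12]])
    # original order preserved
    expect_equal(sel$gene_ids, colnames(m)[sort(match(sel$gene_ids, colnames(m)))])
  }
})

test_that("variance ties at the boundary keep the lower column index", {
  m <- cbind(g1 = c(0, 1, 2), g2 = c(0, 1, 2), g3 = c(0, 0, 0))
  sel <- select_top_variance_genes(m, n_top = 1)
  expect_equal(sel$gene_ids, "g1")
  # n_top larger than gene count returns everything
  expect_equal(ncol(select_top_variance_genes(m, n_top = 10)$values), 3L)
  # single varying gene wins
  m2 <- cbind(g1 = c(5, 5, 5), g2 = c(0, 3, 9), g3 = c(1, 1, 1))
  expect_equal(select_top_variance_genes(m2, n_top = 1)$gene_ids, "g2")
})

test_that("per-cell centering zeroes row means and is idempotent", {
  expect_equal(center_per_cell(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  expect_equal(center_per_cell(matrix(7, 1, 3)), matrix(0, 1, 3))
  set.seed(11)
  m <- matrix(rnorm(50 * 20, mean = 5), 50, 20)
  c1 <- center_per_cell(m)
  expect_lt(max(abs(rowMeans(c1))), 1e-9)
  expect_lt(max(abs(center_per_cell(c1) - c1)), 1e-9)
})

test_that("the pipeline composes the steps in order with provenance", {
  sim <- simulate_zinb_counts(zinb_sim_config(n_cells = 80, n_genes = 300),
                              seed = 5)
  cfg <- preprocess_config(n_top_genes = 100)
  p1 <- preprocess_counts(sim$counts, cfg)
  expect_lte(ncol(p1$values), 100L)
  expect_lt(max(abs(rowMeans(p1$values))), 1e-9)
  expect_equal(dim(p1$raw_counts), dim(p1$values))
  expect_equal(colnames(p1$raw_counts), p1$kept_gene_ids)
  expect_equal(names(p1$provenance),
               c("filter", "log_normalize", "select_top_variance_genes",
                 "center_per_cell"))
  # deterministic
  p2 <- preprocess_counts(sim$counts, cfg)
  expect_identical(p1$values, p2$values)
})
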