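test_that("Student-t soft assignments match hand evaluation", {
  # z at the first center, second center at distance^2 = 2, alpha = 1:
  # q1 = 1 / (1 + 1/3) = 0.75
  Z <- matrix(c(0, 0), 1)
  R <- rbind(c(0, 0), c(1, 1))
  Q <- soft_assign(Z, R, alpha = 1)
  expect_equal(Q[1, 1], 0.75, tolerance = 1e-12)
  # equidistant point splits evenly
  Qm <- soft_assign(matrix(c(0.5, 0.5), 1), R)
  expect_equal(Qm[1, ], c(0.5, 0.5), tolerance = 1e-12)
  set.seed(1)
  Zr <- matrix(rnorm(40), 10, 4); Rr <- matrix(rnorm(12), 3, 4)
  expect_lt(max(abs(rowSums(soft_assign(Zr, Rr)) - 1)), 1e-12)
  expect_error(soft_assign(Zr, Rr[0, , drop = FALSE]), "center")
})

test_that("soft assignments are invariant to a common rotation", {
  set.seed(2)
  Z <- matrix(rnorm(30), 15, 2); R <- matrix(rnorm(6), 3, 2)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(soft_assign(Z %*% rot, R %*% rot), soft_assign(Z, R),
               tolerance = 1e-12)
})

test_that("target distribution sharpens according to its definition", {
  # direct evaluation with f = column sums
  Q <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  f <- colSums(Q)
  W <- sweep(Q^2, 2, f, "/")
  P_expected <- W / rowSums(W)
  expect_equal(target_distribution(Q), P_expected, tolerance = 1e-12)
  expect_equal(P_expected[1, 1], 0.8727, tolerance = 1e-4)
  expect_equal(P_expected[2, 1], 0.4909, tolerance = 1e-4)
  # fixed points: one-hot rows and symmetric uniform
  expect_equal(target_distribution(rbind(c(1, 0))), rbind(c(1, 0)))
  U <- matrix(0.5, 4, 2)
  expect_equal(target_distribution(U), U)
})

test_that("repeated sharpening concentrates mass when clusters are balanced", {
  # with equal cluster frequencies the frequency correction cancels and
  # each squaring strictly concentrates every row on its argmax; balance
  # is enforced by stacking all cyclic column shifts of random rows
  set.seed(3)
  for (i in 1:10) {
    base <- matrix(rexp(15), 5); base <- base / rowSums(base)
    Q <- rbind(base, base[, c(2, 3, 1)], base[, c(3, 1, 2)])
    P1 <- target_distribution(Q)
    P2 <- target_distribution(P1)
    expect_true(all(apply(P1, 1, max) >= apply(Q, 1, max) - 1e-12))
    expect_true(all(apply(P2, 1, max) >= apply(P1, 1, max) - 1e-12))
  }
})

test_that("clustering loss is the discrete KL with brute-force agreement", {
  set.seed(4)
  Q <- matrix(rexp(15), 5); Q <- Q / rowSums(Q)
  P <- target_distribution(Q)
  brute <- sum(P * log(P / Q))
  expect_equal(clustering_loss(P, Q), brute, tolerance = 1e-10)
  expect_equal(clustering_loss(Q, Q), 0)
  expect_gt(clustering_loss(P, Q), 0)   # sharpening moves the target
})

test_that("restarted k-means returns the best of its restarts", {
  set.seed(5)
  Z <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
             matrix(rnorm(100, 8, 0.1), 50, 2))
  km <- init_centers(Z, 2, seed = 1)
  cent <- km$centers[order(km$centers[, 1]), ]
  expect_lt(max(abs(cent[1, ] - c(0, 0))), 0.1)
  expect_lt(max(abs(cent[2, ] - c(8, 8))), 0.1)
  km2 <- init_centers(Z, 2, seed = 1)
  expect_identical(km$centers, km2$centers)
  singles <- sapply(1:5, function(r) {
    set.seed(derive_seed(1, paste0("kmeans", r)))
    suppressWarnings(kmeans(Z, 2, nstart = 1, iter.max = 200))$tot.withinss
  })
  expect_lte(km$inertia, min(singles) + 1e-9)
  expect_error(init_centers(Z[1, , drop = FALSE], 2), "at least")
})

test_that("hard labels take the argmax with ties to the first cluster", {
  Q <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(hard_labels(Q), c(1L, 1L, 2L))
  expect_length(hard_labels(matrix(1 / 3, 7, 3)), 7L)
})
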