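test_that("ARI is 1 for identical partitions and invariant to renaming", {
  a <- rep(1:3, times = c(5, 7, 4))
  expect_equal(ari(a, a), 1.0)
  renamed <- c("x", "y", "z")[a]
  expect_equal(ari(a, renamed), 1.0)
  expect_equal(ari(a, renamed), ari(renamed, a))
  expect_error(ari(a, a[-1]), "length")
})

test_that("ARI of independent random partitions is near zero", {
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    a <- sample(4, 1e4, replace = TRUE)
    b <- sample(4, 1e4, replace = TRUE)
    hits <- hits + (abs(ari(a, b)) < 0.02)
  }
  expect_gte(hits, 38)
})

test_that("ARI and NMI match brute-force contingency computations", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(20:50, 1)
    a <- sample(4, n, replace = TRUE)
    b <- sample(3, n, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-8)
    expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-8)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  }
  # the 2x2 contingency [[2,1],[1,2]] case by direct entropy sums
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
  expect_equal(nmi(a, a), 1.0)
  expect_equal(nmi(a, rep(1, 6)), 0)
})

test_that("NMI agrees with the igraph implementation", {
  skip_if_not_installed("igraph")
  set.seed(3)
  a <- sample(3, 60, replace = TRUE)
  b <- sample(4, 60, replace = TRUE)
  expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
               tolerance = 1e-10)
})

test_that("silhouette separates tight blobs and matches brute force", {
  set.seed(4)
  Z <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 5, 0.05), 20))
  lab <- rep(1:2, each = 20)
  expect_gt(silhouette_score(Z, lab), 0.9)
  for (seed in 1:5) {
    set.seed(seed)
    Zr <- matrix(rnorm(80), 40, 2)
    lr <- sample(3, 40, replace = TRUE)
    expect_equal(silhouette_score(Zr, lr), oracle_silhouette(Zr, lr),
                 tolerance = 1e-10)
  }
  expect_error(silhouette_score(Z, rep(1, 40)), "2 clusters")
})

test_that("Calinski-Harabasz grows with separation and matches brute force", {
  set.seed(5)
  blob <- matrix(rnorm(60, sd = 0.3), 30, 2)
  lab <- rep(1:2, each = 15)
  scores <- sapply(c(1, 3, 9), function(sep) {
    Z <- blob; Z[lab == 2, 1] <- Z[lab == 2, 1] + sep
    calinski_harabasz(Z, lab)
  })
  expect_true(all(diff(scores) > 0))
  for (seed in 1:5) {
    set.seed(seed)
    Z <- matrix(rnorm(90), 45, 2)
    l <- sample(3, 45, replace = TRUE)
    expect_equal(calinski_harabasz(Z, l), oracle_ch(Z, l), tolerance = 1e-8)
  }
  # zero within-cluster scatter guards to +Inf
  Zd <- rbind(matrix(1, 5, 2), matrix(2, 5, 2))
  expect_identical(calinski_harabasz(Zd, rep(1:2, each = 5)), Inf)
  expect_error(calinski_harabasz(Zd, rep(1, 10)), "clusters")
})

test_that("K-NN preservation has the right fixed points and null level", {
  set.seed(6)
  X <- matrix(rnorm(200), 50, 4)
  expect_equal(knn_preservation(X, X, 10), 1.0)
  Y <- matrix(rnorm(150), 50, 3)
  expect_equal(knn_preservation(X, Y, 49), 1.0)   # K = n - 1
  expect_error(knn_preservation(X, Y, 50), "K must")
  # rotation/scale invariance
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  X2 <- matrix(rnorm(100), 50, 2)
  expect_equal(knn_preservation(X2, 3 * (X2 %*% rot), 7), 1.0)
  # independent spaces: overlap concentrates near K / (n - 1)
  vals <- sapply(1:20, function(s) {
    set.seed(s)
    knn_preservation(matrix(rnorm(500 * 3), 500),
                     matrix(rnorm(500 * 3), 500), 50)
  })
  expect_lt(abs(mean(vals) - 50 / 499), 0.03)
})

test_that("K-NN preservation matches the brute-force neighbor overlap", {
  set.seed(7)
  X <- matrix(rnorm(120), 40, 3)
  Y <- X + matrix(rnorm(120, sd = 0.5), 40, 3)
  expect_equal(knn_preservation(X, Y, 5), oracle_knn_preservation(X, Y, 5),
               tolerance = 1e-12)
})

test_that("coefficient of variation matches its definition", {
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  set.seed(8)
  x <- rexp(20)
  expect_equal(coefficient_of_variation(7 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(1), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
})

test_that("evaluate_clustering bundles the requested metrics", {
  set.seed(9)
  Z <- rbind(matrix(rnorm(60, 0, 0.2), 30), matrix(rnorm(60, 4, 0.2), 30))
  truth <- rep(1:2, each = 30)
  rep_ <- evaluate_clustering(Z, truth, truth = truth, X_orig = Z,
                              knn_grid = c(5, 10))
  expect_equal(rep_$ari, 1.0)
  expect_equal(rep_$nmi, 1.0)
  expect_gt(rep_$silhouette, 0.8)
  expect_named(rep_$knn_preservation, c("K5", "K10"))
  expect_equal(rep_$knn_preservation$K5, 1.0)
})
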