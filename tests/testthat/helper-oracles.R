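# Independent brute-force implementations used as oracles. These are
# written from the textbook definitions and deliberately share no code with
# the package internals.

oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  if (h(pa) == 0 || h(pb) == 0) return(0)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  unname(mi / ((h(pa) + h(pb)) / 2))
}

oracle_silhouette <- function(Z, labels) {
  n <- nrow(Z)
  D <- as.matrix(dist(Z))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_ch <- function(Z, labels) {
  n <- nrow(Z); k <- length(unique(labels))
  g <- colMeans(Z)
  b <- 0; w <- 0
  for (l in unique(labels)) {
    zi <- Z[labels == l, , drop = FALSE]
    ci <- colMeans(zi)
    b <- b + nrow(zi) * sum((ci - g)^2)
    for (r in seq_len(nrow(zi))) w <- w + sum((zi[r, ] - ci)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

oracle_knn_preservation <- function(X, Y, K) {
  n <- nrow(X)
  DX <- as.matrix(dist(X)); DY <- as.matrix(dist(Y))
  diag(DX) <- Inf; diag(DY) <- Inf
  fr <- numeric(n)
  for (i in seq_len(n)) {
    nx <- order(DX[i, ])[1:K]
    ny <- order(DY[i, ])[1:K]
    fr[i] <- length(intersect(nx, ny)) / K
  }
  mean(fr)
}

# small deterministic count fixture with ids
make_counts <- function(n = 6, g = 4, seed = 1, max_count = 9) {
  set.seed(seed)
  m <- matrix(sample(0:max_count, n * g, replace = TRUE), n, g)
  dimnames(m) <- list(paste0("c", seq_len(n)), paste0("g", seq_len(g)))
  m
}
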