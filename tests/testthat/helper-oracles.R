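# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths.

# Tanimoto by explicit bit counting
oracle_tanimoto <- function(x, y) {
  a <- 0; b <- 0; cc <- 0
  for (i in seq_along(x)) {
    if (x[i] == 1) a <- a + 1
    if (y[i] == 1) b <- b + 1
    if (x[i] == 1 && y[i] == 1) cc <- cc + 1
  }
  if (a + b == 0) return(1)
  cc / (a + b - cc)
}

# Silhouette by literal definition, one point at a time
oracle_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- sum(d[i, same]) / length(same)
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      idx <- which(labels == cl)
      b <- min(b, sum(d[i, idx]) / length(idx))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Dunn by literal definition
oracle_dunn <- function(d, labels) {
  d <- as.matrix(d)
  cls <- unique(labels)
  inter <- Inf
  diam <- 0
  for (ci in cls) {
    ii <- which(labels == ci)
    if (length(ii) > 1) diam <- max(diam, max(d[ii, ii]))
    for (cj in setdiff(cls, ci)) {
      inter <- min(inter, min(d[ii, which(labels == cj), drop = FALSE]))
    }
  }
  if (diam == 0) return(Inf)
  inter / diam
}

# Upper-tail hypergeometric by exhaustive summation of the pmf
oracle_hyper_upper <- function(k, N, K, n) {
  total <- 0
  for (j in k:min(K, n)) {
    total <- total + choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }
  total
}

# RWR fixed point by dense linear solve: (I - (1-r) M) p = r e
oracle_rwr_solve <- function(graph, seeds, r) {
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  deg <- colSums(A)
  n <- nrow(A)
  e <- numeric(n)
  names(e) <- igraph::V(graph)$name
  e[seeds] <- 1 / length(seeds)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    M[, j] <- if (deg[j] > 0) A[, j] / deg[j] else e
  }
  p <- solve(diag(n) - (1 - r) * M, r * e)
  names(p) <- igraph::V(graph)$name
  p
}

# Adjusted Rand index (external implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Straight transcription of the asymmetric double sigmoid, kept separate
# from the package implementation
oracle_ads <- function(x, a, b, c, d, e, f, dmax) {
  num <- a + b / (1 + exp(-(x - c + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - c - d / 2) / f)))
  min(max(num / dmax, 1e-6), 1)
}
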