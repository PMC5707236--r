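# Independent brute-force oracles, deliberately coded from the definitions
# with none of the package's internals (R loops + Floyd-Warshall instead of
# compiled Dijkstra).

fw_distances <- function(len) {
  n <- nrow(len)
  d <- len
  d[d <= 0 | !is.finite(d)] <- Inf
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_eff <- function(W, weighted) {
  n <- nrow(W)
  len <- if (weighted) ifelse(W > 0, 1 / W, Inf) else ifelse(W > 0, 1, Inf)
  d <- fw_distances(len)
  tot <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  tot / (n * (n - 1))
}

oracle_local_eff <- function(W, weighted) {
  n <- nrow(W)
  out <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(W[u, ] > 0 & seq_len(n) != u)
    k <- length(nb)
    if (k < 2) next
    sub <- W[nb, nb, drop = FALSE]
    len <- if (weighted) ifelse(sub > 0, (1 / sub)^(1 / 3), Inf)
    else ifelse(sub > 0, 1, Inf)
    d <- fw_distances(len)
    acc <- 0
    for (a in seq_len(k))
      for (b in seq_len(k)) {
        if (a == b || !is.finite(d[a, b]) || d[a, b] <= 0) next
        acc <- acc + if (weighted)
          W[u, nb[a]]^(1 / 3) * W[u, nb[b]]^(1 / 3) / d[a, b]
        else 1 / d[a, b]
      }
    out[u] <- acc / (k * (k - 1))
  }
  out
}

oracle_modularity <- function(W, labels) {
  two_m <- sum(W)
  s <- rowSums(W)
  n <- nrow(W)
  q <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (labels[i] == labels[j])
        q <- q + W[i, j] - s[i] * s[j] / two_m
  q / two_m
}

oracle_participation <- function(W, labels, weighted) {
  if (!weighted) W <- (W > 0) * 1
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(W[i, ])
    if (ki <= 0) next
    acc <- 0
    for (m in unique(labels)) acc <- acc + (sum(W[i, labels == m]) / ki)^2
    out[i] <- 1 - acc
  }
  out
}

# random symmetric nonnegative test graph with zero diagonal
rand_graph <- function(n, density = 0.5, weighted = TRUE, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- runif(length(ut)) < density
  A[ut[on]] <- if (weighted) runif(sum(on), 0.1, 1) else 1
  A + t(A)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
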