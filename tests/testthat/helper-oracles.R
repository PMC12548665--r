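# Brute-force graph-metric oracles, independent of the package's igraph
# implementation. Everything works on a binary symmetric adjacency matrix
# and enumerates explicitly; intended for n <= 12.

oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] > 0)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# number of shortest paths s -> every node, by DP over BFS levels
oracle_sigma <- function(adj, s, d) {
  n <- nrow(adj)
  sigma <- numeric(n)
  sigma[s] <- 1
  for (lev in sort(unique(d[is.finite(d) & d > 0]))) {
    for (v in which(d == lev)) {
      pred <- which(adj[v, ] > 0 & d == lev - 1)
      sigma[v] <- sum(sigma[pred])
    }
  }
  sigma
}

oracle_betweenness <- function(adj, normalized = FALSE) {
  n <- nrow(adj)
  btw <- numeric(n)
  dist <- lapply(seq_len(n), function(s) oracle_bfs_dist(adj, s))
  sig <- lapply(seq_len(n), function(s) oracle_sigma(adj, s, dist[[s]]))
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[[s]][t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[[s]][v]) && is.finite(dist[[t]][v]) &&
          dist[[s]][v] + dist[[t]][v] == dist[[s]][t]) {
        btw[v] <- btw[v] + sig[[s]][v] * sig[[t]][v] / sig[[s]][t]
      }
    }
  }
  if (normalized && n > 2) btw <- btw * 2 / ((n - 1) * (n - 2))
  btw
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, 1)
}

oracle_all_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_all_dist(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, 1)
}

# modularity value of a given membership vector (definition-level recompute)
oracle_modularity_value <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    ec <- sum(adj[idx, idx]) / 2
    dc <- sum(adj[idx, ])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# random symmetric binary adjacency with no self loops
random_binary_adj <- function(n, p = 0.4) {
  a <- matrix(stats::rbinom(n * n, 1, p), n)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0
  a
}
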