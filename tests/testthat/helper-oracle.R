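# Brute-force graph-metric oracle, independent of the package's igraph
# route: Floyd-Warshall shortest paths and direct neighbour enumeration.

oracleDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracleMetrics <- function(adj) {
  n <- nrow(adj)
  deg <- integer(n)
  cc <- numeric(n)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    deg[i] <- k
    if (k >= 2) {
      ei <- 0
      for (a in seq_len(k - 1)) for (b in (a + 1):k)
        if (adj[nb[a], nb[b]] == 1) ei <- ei + 1
      cc[i] <- 2 * ei / (k * (k - 1))
      dsub <- oracleDistances(adj[nb, nb, drop = FALSE])
      inv <- 1 / dsub
      diag(inv) <- 0
      le[i] <- sum(inv) / (k * (k - 1))
    }
  }
  d <- oracleDistances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  off <- d[upper.tri(d)]
  list(degree = deg, cc_node = cc, cc = mean(cc), le = mean(le),
       ge = sum(inv) / (n * (n - 1)),
       path_length = mean(off[is.finite(off)]))
}

## named binary graph from an adjacency matrix
mkGraph <- function(adj, sparsity = 0.5) {
  n <- nrow(adj)
  labs <- paste0("n", seq_len(n))
  dimnames(adj) <- list(labs, labs)
  BinaryGraph(adj, sparsity, labels = labs)
}

## adjacency from an edge list on n nodes
adjFromEdges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  a
}

## small synthetic recording fixtures
singlePairCoupling <- function(noise_sd = 0.05, strength = 1,
                               lag = pi / 2, mixing = 0) {
  list(alpha = couplingSpec("alpha",
    data.frame(from = "C3", to = "F3", lag = lag, strength = strength,
               freq = 10),
    noise_sd = noise_sd, mixing_strength = mixing))
}

sineRecording <- function(freq, fs = 500, dur = 4, labels = c("x", "A1", "A2")) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  dat <- rbind(sin(2 * pi * freq * t),
               matrix(0, length(labels) - 1L, length(t)))
  EEGRecording(dat, fs = fs, labels = labels)
}
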