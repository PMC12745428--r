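#' Sparsity threshold profile
#'
#' The seven sparsity levels at which binary networks are built: 17% to
#' 47% of the strongest connections, in 5% increments. Per-subject metrics
#' are summarized by their mean across levels (an area-under-curve
#' equivalent for evenly spaced levels).
#'
#' @return Numeric vector of sparsity fractions.
#' @export
thresholdProfile <- function() seq(0.17, 0.47, by = 0.05)

#' Binarize a connectivity matrix at a sparsity level
#'
#' Keeps the `k = round(sparsity * N(N-1)/2)` strongest upper-triangle
#' weights as edges of an undirected, unweighted graph. Ties at the cut
#' are broken by fixed lexicographic `(node_i, node_j)` order so the
#' result is deterministic. A warning is issued when the resulting graph
#' is disconnected.
#'
#' @param m a [ConnectivityMatrix-class].
#' @param sparsity fraction of possible edges to retain, in `(0, 1]`.
#' @return A [BinaryGraph-class].
#' @examples
#' v <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' v[upper.tri(v)] <- c(0.9, 0.8, 0.6, 0.7, 0.5, 0.4)
#' v <- v + t(v)
#' g <- thresholdBySparsity(ConnectivityMatrix(v, "alpha"), 0.5)
#' adjacency(g)
#' @export
thresholdBySparsity <- function(m, sparsity) {
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must lie in (0, 1]")
  v <- m@values
  n <- nrow(v)
  if (all(v == 0)) stop("all-zero connectivity matrix: no ranking possible")
  ut <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[upper.tri(v)]
  k <- round(sparsity * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(k)]
  adj <- matrix(0, n, n, dimnames = dimnames(v))
  adj[ut[keep, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  g <- BinaryGraph(adj, sparsity, labels = m@labels)
  if (graphComponents(g) > 1L)
    warning(sprintf("graph at sparsity %.2f is disconnected", sparsity))
  g
}

asIgraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g@adjacency, mode = "undirected")
}

graphComponents <- function(g) {
  igraph::components(asIgraph(g))$no
}

#' Node degree
#'
#' Number of edges incident to each node (adjacency row sums).
#'
#' @param g a [BinaryGraph-class].
#' @return Named integer vector, one entry per node.
#' @export
nodeDegree <- function(g) {
  stats::setNames(as.integer(rowSums(g@adjacency)), g@labels)
}

#' Clustering coefficient
#'
#' Per-node `CC_i = 2 E_i / (k_i (k_i - 1))`, where `E_i` counts edges
#' among the neighbors of node i and `k_i` is its degree; nodes with
#' `k_i < 2` are assigned `CC_i = 0`. The network coefficient is the mean
#' over all N nodes.
#'
#' @param g a [BinaryGraph-class].
#' @return List with `node` (per-node CC) and `mean` (network CC).
#' @export
clusteringCoefficient <- function(g) {
  a <- g@adjacency
  n <- nrow(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    ei <- sum(a[nb, nb]) / 2
    cc[i] <- 2 * ei / (k * (k - 1))
  }
  list(node = stats::setNames(cc, g@labels), mean = mean(cc))
}

## all-pairs shortest path matrix (hops); Inf for unreachable
shortestPaths <- function(g) {
  igraph::distances(asIgraph(g))
}

#' Global efficiency
#'
#' Mean of the reciprocal shortest path lengths over all ordered node
#' pairs, `GE = 1/(N(N-1)) * sum_{i != j} 1/L_ij`; unreachable pairs
#' contribute `1/Inf = 0`.
#'
#' @param g a [BinaryGraph-class].
#' @return Scalar in `[0, 1]`.
#' @export
globalEfficiency <- function(g) {
  d <- shortestPaths(g)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the efficiency of the subgraph induced by its
#' neighbors (shortest paths restricted to that subgraph); nodes with
#' degree `< 2` contribute 0. The network value is the mean over all N
#' nodes.
#'
#' @param g a [BinaryGraph-class].
#' @return Scalar in `[0, 1]`.
#' @export
localEfficiency <- function(g) {
  a <- g@adjacency
  n <- nrow(a)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    sub <- igraph::graph_from_adjacency_matrix(a[nb, nb, drop = FALSE],
                                               mode = "undirected")
    d <- igraph::distances(sub)
    inv <- 1 / d
    diag(inv) <- 0
    le[i] <- sum(inv) / (k * (k - 1))
  }
  mean(le)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected node pairs; disconnected
#' pairs are excluded (their count is reported in the `"n_disconnected"`
#' attribute).
#'
#' @param g a [BinaryGraph-class].
#' @return Scalar (`>= 1` for graphs with at least one edge), with
#'   attribute `n_disconnected` counting excluded unordered pairs.
#' @export
characteristicPathLength <- function(g) {
  d <- shortestPaths(g)
  off <- d[upper.tri(d)]
  bad <- sum(!is.finite(off))
  val <- mean(off[is.finite(off)])
  attr(val, "n_disconnected") <- bad
  val
}

#' Degree-preserving random reference
#'
#' Clustering coefficient and characteristic path length of
#' degree-preserving random rewirings of the graph (double-edge swaps, at
#' least `10 * |E|` attempted swaps per realization), averaged over
#' realizations. A complete graph admits no swaps; its own metrics are
#' returned with a warning.
#'
#' @param g a [BinaryGraph-class] with at least one edge.
#' @param n_realizations number of rewired realizations (default 100).
#' @param seed integer seed for reproducibility.
#' @return List with `c_rand`, `l_rand`, and `degrees` (the preserved
#'   degree sequence).
#' @export
randomReference <- function(g, n_realizations = 100, seed = 1) {
  a <- g@adjacency
  n <- nrow(a)
  ne <- sum(a) / 2
  if (ne < 1) stop("graph has no edges")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  if (ne == n * (n - 1) / 2) {
    warning("complete graph: no degree-preserving swap possible")
    cc <- clusteringCoefficient(g)$mean
    L <- as.numeric(characteristicPathLength(g))
    return(list(c_rand = cc, l_rand = L, degrees = nodeDegree(g)))
  }
  ig <- asIgraph(g)
  niter <- 10L * as.integer(ne)
  withSeed(seed, {
    cs <- numeric(n_realizations)
    ls <- numeric(n_realizations)
    for (r in seq_len(n_realizations)) {
      rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = niter))
      adj <- as.matrix(igraph::as_adjacency_matrix(rg))
      bg <- BinaryGraph(adj, g@sparsity, labels = g@labels)
      cs[r] <- clusteringCoefficient(bg)$mean
      ls[r] <- as.numeric(characteristicPathLength(bg))
    }
    list(c_rand = mean(cs), l_rand = mean(ls), degrees = nodeDegree(g))
  })
}

#' Small-worldness
#'
#' `SW = (C / C_rand) / (L / L_rand)` against the degree-preserving
#' random reference; `SW > 1` indicates small-world organization
#' (clustering above, path length near, a degree-matched random network).
#'
#' @inheritParams randomReference
#' @return Scalar with logical attribute `small_world` (`SW > 1`).
#' @export
smallWorldness <- function(g, n_realizations = 100, seed = 1) {
  cc <- clusteringCoefficient(g)$mean
  L <- as.numeric(characteristicPathLength(g))
  ref <- suppressWarnings(randomReference(g, n_realizations, seed))
  sw <- (cc / ref$c_rand) / (L / ref$l_rand)
  attr(sw, "small_world") <- sw > 1
  sw
}

#' All network metrics of one binary graph
#'
#' @inheritParams randomReference
#' @param include_sw compute the random reference and small-worldness
#'   (the expensive part); if `FALSE`, `c_rand`, `l_rand` and `sw` are NA.
#' @return List with `degree`, `cc_node`, `cc`, `le`, `ge`,
#'   `path_length`, `n_disconnected`, `c_rand`, `l_rand`, `sw`.
#' @export
networkMetrics <- function(g, n_realizations = 100, seed = 1,
                           include_sw = TRUE) {
  cc <- clusteringCoefficient(g)
  L <- characteristicPathLength(g)
  out <- list(degree = nodeDegree(g), cc_node = cc$node, cc = cc$mean,
              le = localEfficiency(g), ge = globalEfficiency(g),
              path_length = as.numeric(L),
              n_disconnected = attr(L, "n_disconnected"),
              c_rand = NA_real_, l_rand = NA_real_, sw = NA_real_)
  if (include_sw) {
    ref <- suppressWarnings(randomReference(g, n_realizations, seed))
    out$c_rand <- ref$c_rand
    out$l_rand <- ref$l_rand
    out$sw <- (out$cc / ref$c_rand) / (out$path_length / ref$l_rand)
  }
  out
}

#' Network metrics across the sparsity threshold profile
#'
#' Builds a binary graph at every sparsity level of the profile, computes
#' all metrics at each level, and aggregates them by the mean across
#' levels. Per-level values are retained for audit.
#'
#' @param m a [ConnectivityMatrix-class].
#' @param profile sparsity levels (default [thresholdProfile()]).
#' @param n_realizations random-reference realizations per level.
#' @param seed integer seed.
#' @param include_sw compute small-worldness (default `TRUE`).
#' @return List of class `ThresholdMetrics` with components `levels`
#'   (data.frame, one row per sparsity level), `aggregate` (named means
#'   across levels of `cc`, `le`, `ge`, `path_length`, `sw`),
#'   `node_degree` and `node_cc` (levels x nodes matrices), and `band`.
#' @export
metricsOverThresholds <- function(m, profile = thresholdProfile(),
                                  n_realizations = 100, seed = 1,
                                  include_sw = TRUE) {
  if (is.unsorted(profile, strictly = TRUE) ||
      any(profile <= 0 | profile >= 1))
    stop("profile must be strictly increasing within (0, 1)")
  seeds <- deriveSeeds(seed, length(profile))
  n <- length(m@labels)
  rows <- vector("list", length(profile))
  ndeg <- matrix(NA_integer_, length(profile), n,
                 dimnames = list(NULL, m@labels))
  ncc <- matrix(NA_real_, length(profile), n,
                dimnames = list(NULL, m@labels))
  for (i in seq_along(profile)) {
    g <- suppressWarnings(thresholdBySparsity(m, profile[i]))
    mt <- networkMetrics(g, n_realizations, seeds[i], include_sw)
    ndeg[i, ] <- mt$degree
    ncc[i, ] <- mt$cc_node
    rows[[i]] <- data.frame(sparsity = profile[i], cc = mt$cc, le = mt$le,
                            ge = mt$ge, path_length = mt$path_length,
                            sw = mt$sw, c_rand = mt$c_rand,
                            l_rand = mt$l_rand,
                            n_disconnected = mt$n_disconnected)
  }
  levels <- do.call(rbind, rows)
  agg <- colMeans(levels[, c("cc", "le", "ge", "path_length", "sw")])
  structure(list(levels = levels, aggregate = agg, node_degree = ndeg,
                 node_cc = ncc, band = m@band),
            class = "ThresholdMetrics")
}

#' @export
print.ThresholdMetrics <- function(x, ...) {
  cat("ThresholdMetrics [band ", x$band, "], ", nrow(x$levels),
      " sparsity levels\n", sep = "")
  print(round(x$aggregate, 4))
  invisible(x)
}
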