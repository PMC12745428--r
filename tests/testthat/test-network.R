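cmFromWeights <- function(w) {
  ConnectivityMatrix(w, band = "alpha", labels = rownames(w))
}

test_that("sparsity thresholding keeps the k strongest edges with fixed ties", {
  labs <- c("A", "B", "C", "D")
  w <- matrix(0, 4, 4, dimnames = list(labs, labs))
  w["A", "B"] <- 0.9; w["A", "C"] <- 0.8; w["A", "D"] <- 0.7
  w["B", "C"] <- 0.6; w["B", "D"] <- 0.5; w["C", "D"] <- 0.4
  w <- w + t(w)
  g <- suppressWarnings(thresholdBySparsity(cmFromWeights(w), 0.5))
  a <- adjacency(g)
  expect_identical(sum(a) / 2, 3)
  expect_true(all(a["A", c("B", "C", "D")] == 1))
  ## equal weights: ties resolved lexicographically (A-B, A-C, A-D)
  weq <- matrix(0.5, 4, 4, dimnames = list(labs, labs)); diag(weq) <- 0
  geq <- suppressWarnings(thresholdBySparsity(cmFromWeights(weq), 0.5))
  aeq <- adjacency(geq)
  expect_identical(sum(aeq) / 2, 3)
  expect_true(all(aeq["A", c("B", "C", "D")] == 1))
  ## full sparsity: complete graph on 19 nodes has 171 edges
  labs19 <- standardMontage()$labels
  w19 <- matrix(runif(19 * 19), 19, dimnames = list(labs19, labs19))
  w19 <- (w19 + t(w19)) / 2; diag(w19) <- 0
  k19 <- thresholdBySparsity(cmFromWeights(w19), 1)
  expect_identical(sum(adjacency(k19)) / 2, 171)
  expect_error(thresholdBySparsity(cmFromWeights(w19 * 0), 0.2), "zero")
  expect_error(thresholdBySparsity(cmFromWeights(w19), 0), "sparsity")
  expect_warning(thresholdBySparsity(cmFromWeights(w19), 0.05),
                 "disconnected")
})

test_that("metric closed forms hold on canonical graphs", {
  ## complete graph
  kn <- mkGraph(adjFromEdges(5, combn(5, 2, simplify = FALSE)))
  expect_true(all(nodeDegree(kn) == 4L))
  expect_identical(clusteringCoefficient(kn)$mean, 1)
  expect_identical(globalEfficiency(kn), 1)
  expect_identical(localEfficiency(kn), 1)
  expect_identical(as.numeric(characteristicPathLength(kn)), 1)
  ## star on 5 nodes
  star <- mkGraph(adjFromEdges(5, lapply(2:5, function(j) c(1, j))))
  expect_identical(unname(nodeDegree(star)), c(4L, 1L, 1L, 1L, 1L))
  expect_identical(clusteringCoefficient(star)$mean, 0)
  expect_identical(localEfficiency(star), 0)
  ## path graphs
  p3 <- mkGraph(adjFromEdges(3, list(c(1, 2), c(2, 3))))
  expect_equal(globalEfficiency(p3), 5 / 6)
  expect_equal(as.numeric(characteristicPathLength(p3)), 4 / 3)
  p4 <- mkGraph(adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4))))
  expect_equal(globalEfficiency(p4), 13 / 18)
  expect_identical(unname(nodeDegree(p4)), c(1L, 2L, 2L, 1L))
  ## K4 minus one edge: mean CC = 5/6
  k4e <- mkGraph(adjFromEdges(4, list(c(1, 2), c(1, 3), c(1, 4),
                                      c(2, 3), c(2, 4))))
  cc <- clusteringCoefficient(k4e)
  expect_equal(unname(cc$node), c(2 / 3, 2 / 3, 1, 1))
  expect_equal(cc$mean, 5 / 6)
  ## ring of 4: L = 4/3
  r4 <- mkGraph(adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))))
  expect_equal(as.numeric(characteristicPathLength(r4)), 4 / 3)
  ## triangle plus pendant: oracle-computed local efficiency
  tp <- mkGraph(adjFromEdges(4, list(c(1, 2), c(1, 3), c(2, 3), c(1, 4))))
  expect_equal(localEfficiency(tp), oracleMetrics(adjacency(tp))$le)
})

test_that("metrics match the brute-force oracle on all connected 5-node graphs", {
  cnt <- 0L
  worst <- 0
  for (code in 0:(2^10 - 1)) {
    bits <- as.integer(intToBits(code))[1:10]
    adj <- matrix(0, 5, 5)
    adj[upper.tri(adj)] <- bits
    adj <- adj + t(adj)
    if (any(!is.finite(oracleDistances(adj)))) next  # disconnected
    o <- oracleMetrics(adj)
    g <- mkGraph(adj)
    cnt <- cnt + 1L
    mt <- networkMetrics(g, include_sw = FALSE)
    worst <- max(worst,
                 max(abs(mt$degree - o$degree)), abs(mt$cc - o$cc),
                 abs(mt$ge - o$ge), abs(mt$le - o$le),
                 abs(mt$path_length - o$path_length))
  }
  expect_lt(worst, 1e-12)
  expect_identical(cnt, 728L)  # connected labeled graphs on 5 nodes
})

test_that("random references preserve degrees; small-world behaves", {
  ## ring lattice N=20 (emulated on 19 nodes is fine for the invariant):
  ## build a WS-style ring with k=4 on the montage labels
  labs <- standardMontage()$labels
  n <- length(labs)
  adj <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (d in 1:2) {
    j <- (i - 1 + d) %% n + 1
    adj[i, j] <- adj[j, i] <- 1
  }
  g <- BinaryGraph(adj, sum(adj) / 2 / choose(n, 2), labels = labs)
  ref <- randomReference(g, n_realizations = 20, seed = 42)
  expect_identical(ref$degrees, nodeDegree(g))
  ## rewired lattices lose clustering
  expect_lt(ref$c_rand, clusteringCoefficient(g)$mean / 2)
  ## every single realization preserves the degree sequence
  ig <- wpliNet:::asIgraph(g)
  withr::with_seed(1, {
    for (r in 1:5) {
      rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = 400))
      expect_identical(igraph::degree(rg), igraph::degree(ig))
    }
  })
  ## complete graph: no swap possible, SW = 1
  kadj <- matrix(1, n, n, dimnames = list(labs, labs)); diag(kadj) <- 0
  kg <- BinaryGraph(kadj, 1, labels = labs)
  expect_warning(refk <- randomReference(kg, 5, seed = 1), "complete")
  expect_identical(refk$c_rand, 1)
  expect_equal(suppressWarnings(as.numeric(smallWorldness(kg, 5, seed = 1))), 1)
})

test_that("seeded Watts-Strogatz graphs are small-world, dense random ones are not", {
  sw_ws <- withr::with_seed(10, replicate(8, {
    ig <- igraph::sample_smallworld(1, 20, 2, 0.1)
    adj <- as.matrix(igraph::as_adjacency_matrix(ig))
    dimnames(adj) <- list(paste0("n", 1:20), paste0("n", 1:20))
    g <- BinaryGraph(adj, sum(adj) / 2 / choose(20, 2),
                     labels = rownames(adj))
    as.numeric(smallWorldness(g, n_realizations = 12,
                              seed = sample.int(1e6, 1)))
  }))
  expect_true(mean(sw_ws > 1) >= 0.95)
  sw_er <- withr::with_seed(11, replicate(8, {
    ig <- igraph::sample_gnp(20, 0.5)
    adj <- as.matrix(igraph::as_adjacency_matrix(ig))
    dimnames(adj) <- list(paste0("n", 1:20), paste0("n", 1:20))
    g <- BinaryGraph(adj, sum(adj) / 2 / choose(20, 2),
                     labels = rownames(adj))
    as.numeric(smallWorldness(g, n_realizations = 12,
                              seed = sample.int(1e6, 1)))
  }))
  expect_gte(mean(sw_er), 0.8)
  expect_lte(mean(sw_er), 1.2)
})

test_that("threshold-profile metrics aggregate, stay rank-invariant and
          permutation-invariant", {
  labs <- standardMontage()$labels
  set.seed(12)
  w <- matrix(runif(19 * 19), 19, dimnames = list(labs, labs))
  w <- (w + t(w)) / 2; diag(w) <- 0
  m <- cmFromWeights(w)
  tm <- suppressWarnings(
    metricsOverThresholds(m, n_realizations = 4, seed = 3))
  expect_identical(nrow(tm$levels), 7L)
  expect_equal(unname(tm$aggregate["ge"]), mean(tm$levels$ge))
  ## strictly monotone transform of the weights changes nothing
  w2 <- w / 2 + 0.4; diag(w2) <- 0
  tm2 <- suppressWarnings(
    metricsOverThresholds(cmFromWeights(w2), n_realizations = 4,
                          seed = 3))
  expect_equal(tm$levels, tm2$levels)
  ## GE and CC are monotone non-decreasing on the nested edge sets
  expect_true(all(diff(tm$levels$ge) >= -1e-12))
  expect_true(all(diff(tm$levels$cc) >= -1e-12))
  ## node relabeling permutes, but does not change, the metrics
  perm <- sample(19)
  wp <- w[perm, perm]
  tmp <- suppressWarnings(
    metricsOverThresholds(cmFromWeights(wp), n_realizations = 4, seed = 3))
  expect_equal(tm$levels[, c("cc", "le", "ge", "path_length")],
               tmp$levels[, c("cc", "le", "ge", "path_length")])
  ## constant ranking across levels: aggregate equals per-level values
  expect_error(metricsOverThresholds(m, profile = c(0.5, 0.2)), "profile")
})
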