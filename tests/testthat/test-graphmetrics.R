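pathGraph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  rownames(A) <- colnames(A) <- letters[seq_len(n)]
  A
}

starGraph <- function(leaves) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  rownames(A) <- colnames(A) <- c("center", paste0("leaf", seq_len(leaves)))
  A
}

completeGraph <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  rownames(A) <- colnames(A) <- paste0("n", seq_len(n))
  A
}

test_that("betweenness matches closed forms on path and star", {
  bc <- betweennessCentrality(pathGraph(3))
  expect_equal(unname(bc), c(0, 1, 0))
  bc <- betweennessCentrality(starGraph(4))
  expect_equal(unname(bc), c(choose(4, 2), 0, 0, 0, 0))
})

test_that("clustering reproduces the three worked neighbourhood examples", {
  # a hub node with three mutually unconnected neighbours
  A <- starGraph(3)
  expect_equal(unname(clusteringCoefficient(A)["center"]), 0)
  # exactly one of the three neighbour pairs connected
  A["leaf1", "leaf2"] <- A["leaf2", "leaf1"] <- 1
  expect_equal(unname(clusteringCoefficient(A)["center"]), 1 / 3)
  expect_equal(round(clusteringCoefficient(A)[["center"]], 2), 0.33)
  # all neighbour pairs connected
  A["leaf1", "leaf3"] <- A["leaf3", "leaf1"] <- 1
  A["leaf2", "leaf3"] <- A["leaf3", "leaf2"] <- 1
  expect_equal(unname(clusteringCoefficient(A)["center"]), 1)
})

test_that("efficiency metrics match closed forms", {
  expect_equal(unname(globalEfficiencyNode(completeGraph(5))), rep(1, 5))
  # isolated node contributes zero everywhere
  A <- rbind(cbind(completeGraph(3), 0), 0)
  rownames(A) <- colnames(A) <- paste0("n", 1:4)
  expect_equal(unname(globalEfficiencyNode(A)["n4"]), 0)
  # path a-b-c-d: E_glob(a) = (1 + 1/2 + 1/3)/3
  expect_equal(unname(globalEfficiencyNode(pathGraph(4))["a"]), 11 / 18)
  # triangle: every node's neighbours are adjacent
  expect_equal(unname(localEfficiency(completeGraph(3))), rep(1, 3))
  expect_equal(unname(localEfficiency(starGraph(4))["center"]), 0)
})

test_that("density identities hold", {
  expect_equal(unname(nodeDensity(completeGraph(6))), rep(1, 6))
  expect_equal(wholeDensity(completeGraph(6)), 1)
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unname(nodeDensity(A)), rep(0, 4))
  set.seed(8)
  for (i in 1:10) {
    A <- randomGraph(sample(3:9, 1))
    expect_equal(mean(nodeDensity(A)), wholeDensity(A))
  }
})

test_that("complete graphs pin all metrics at their extremes", {
  for (n in 3:8) {
    A <- completeGraph(n)
    expect_equal(unname(betweennessCentrality(A)), rep(0, n))
    expect_equal(unname(clusteringCoefficient(A)), rep(1, n))
    expect_equal(unname(localEfficiency(A)), rep(1, n))
    expect_equal(unname(globalEfficiencyNode(A)), rep(1, n))
    expect_equal(unname(nodeDensity(A)), rep(1, n))
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    A <- randomGraph(n)
    perm <- sample(n)
    B <- A[perm, perm]
    expect_equal(unname(betweennessCentrality(B)),
                 unname(betweennessCentrality(A))[perm])
    expect_equal(unname(clusteringCoefficient(B)),
                 unname(clusteringCoefficient(A))[perm])
    expect_equal(unname(localEfficiency(B)),
                 unname(localEfficiency(A))[perm])
    expect_equal(unname(globalEfficiencyNode(B)),
                 unname(globalEfficiencyNode(A))[perm])
  }
})

test_that("adding an edge never decreases efficiency or density", {
  set.seed(18)
  for (i in 1:10) {
    A <- randomGraph(7, 0.3)
    off <- which(upper.tri(A) & A == 0)
    if (!length(off)) next
    B <- A
    pick <- sample(off, 1)
    B[pick] <- 1
    B <- pmax(B, t(B))
    expect_true(all(globalEfficiencyNode(B) >=
                      globalEfficiencyNode(A) - 1e-12))
    expect_true(all(nodeDensity(B) >= nodeDensity(A)))
  }
})

test_that("metrics agree with igraph on random graphs", {
  set.seed(19)
  for (i in 1:30) {
    A <- randomGraph(sample(4:12, 1))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(unname(betweennessCentrality(A)),
                 unname(igraph::betweenness(g)), tolerance = 1e-10)
    expect_equal(unname(clusteringCoefficient(A)),
                 unname(igraph::transitivity(g, type = "localundirected",
                                             isolates = "zero")),
                 tolerance = 1e-10)
    expect_equal(wholeGlobalEfficiency(A),
                 igraph::global_efficiency(g), tolerance = 1e-10)
  }
})

test_that("two disjoint triangles partition with Q = 0.5", {
  A <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  }
  part <- louvainCommunities(A, seed = 1)
  expect_equal(part$Q, 0.5)
  expect_true(samePartition(part$membership, rep(1:2, each = 3)))
})

test_that("edgeless graphs yield singletons with Q = 0", {
  A <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  part <- louvainCommunities(A, seed = 1)
  expect_equal(unname(part$membership), 1:5)
  expect_equal(part$Q, 0)
})

test_that("reported Q equals an independent modularity recomputation", {
  set.seed(23)
  for (i in 1:20) {
    A <- randomGraph(sample(5:12, 1), 0.35)
    part <- louvainCommunities(A, seed = i)
    expect_equal(part$Q, oracleModularity(A, part$membership),
                 tolerance = 1e-12)
    expect_equal(part$Q, modularityQ(A, part$membership),
                 tolerance = 1e-12)
  }
})

test_that("isolated nodes stay singleton communities", {
  A <- rbind(cbind(completeGraph(3), 0), 0)
  rownames(A) <- colnames(A) <- paste0("n", 1:4)
  part <- louvainCommunities(A, seed = 2)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(sum(part$membership == part$membership[["n4"]]), 1)
})

test_that("hub rule flags only far-outlying betweenness", {
  expect_equal(hubNodes(setNames(rep(2, 5), letters[1:5])), character(0))
  bc <- setNames(c(0, 0, 0, 0, 10), letters[1:5])
  # mean 2, sd ~4.47: only the 10 clears mean + 1.5 sd
  expect_equal(hubNodes(bc), "e")
  expect_equal(hubNodes(betweennessCentrality(starGraph(5))), "center")
})

test_that("nodeMetrics assembles a coherent per-node table", {
  set.seed(27)
  A <- randomGraph(10, 0.35)
  m <- nodeMetrics(A, seed = 3)
  expect_identical(m$node, rownames(A))
  expect_equal(m$density, m$degree / (nrow(A) - 1))
  expect_true(all(m$clustering[m$degree < 2] == 0))
  expect_true(all(is.finite(as.matrix(m[, 2:7]))))
  expect_equal(attr(m, "Q"), modularityQ(A, m$community),
               tolerance = 1e-12)
  expect_identical(m$hub, m$node %in%
                     hubNodes(setNames(m$betweenness, m$node)))
})
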