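#' Accessors for CognitiveGraph
#'
#' \code{adjacency} returns the binary adjacency matrix,
#' \code{nodeNames} the node labels.
#'
#' @param x a \code{\linkS4class{CognitiveGraph}} (or a plain adjacency
#'   matrix where a metric function is documented to accept one).
#' @name CognitiveGraph-accessors
NULL

#' @rdname CognitiveGraph-accessors
setMethod("adjacency", "CognitiveGraph", function(x) x@adjacency)

#' @rdname CognitiveGraph-accessors
setMethod("nodeNames", "CognitiveGraph", function(x) rownames(x@adjacency))

setMethod("show", "CognitiveGraph", function(object) {
  A <- object@adjacency
  cat("CognitiveGraph:", nrow(A), "nodes,", sum(A) / 2, "edges\n")
  cat(sprintf("  group: %s | alpha: %s | negative edges: %s\n",
              object@group, format(object@alpha),
              object@negativePolicy))
  if (length(object@covariates)) {
    cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
  }
})

## Accept either a CognitiveGraph or a bare adjacency matrix.
asAdjacency <- function(graph) {
  A <- if (is(graph, "CognitiveGraph")) graph@adjacency else as.matrix(graph)
  if (!isBinaryAdjacency(A)) {
    stopf("expected a binary symmetric adjacency matrix with zero diagonal")
  }
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- paste0("node", seq_len(nrow(A)))
  }
  A
}

## BFS geodesic distances from source s; Inf for unreachable nodes.
.bfsDist <- function(nb, n, s) {
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(nb[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

.neighborList <- function(A) {
  lapply(seq_len(nrow(A)), function(i) which(A[i, ] > 0))
}

#' Betweenness centrality (unnormalized)
#'
#' For each node v, the sum over unordered node pairs \{s, t\} (both
#' distinct from v) of the fraction of shortest s-t paths passing
#' through v. Computed with Brandes' dependency-accumulation algorithm;
#' disconnected pairs contribute nothing. Values are left unnormalized,
#' matching the reference-toolbox convention; divide by
#' \code{(N-1)(N-2)/2} if a normalized value is wanted.
#'
#' @param graph a \code{\linkS4class{CognitiveGraph}} or binary
#'   adjacency matrix.
#' @return named numeric vector of betweenness values.
#' @export
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
#' betweennessCentrality(A)  # middle node lies on the single pair: 1
betweennessCentrality <- function(graph) {
  A <- asAdjacency(graph)
  n <- nrow(A)
  nb <- .neighborList(A)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); sigma <- numeric(n)
    dist[s] <- 0L; sigma[s] <- 1
    preds <- vector("list", n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L
    order <- integer(0)
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      order <- c(order, v)
      for (w in nb[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order)) {
      for (u in preds[[v]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  setNames(bc / 2, rownames(A))  # each unordered pair counted from both ends
}

#' Clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected:
#' \code{C(v) = 2 e_N(v) / (k_v (k_v - 1))}, zero for degree < 2.
#'
#' @inheritParams betweennessCentrality
#' @return named numeric vector in [0, 1].
#' @export
clusteringCoefficient <- function(graph) {
  A <- asAdjacency(graph)
  k <- rowSums(A)
  cc <- numeric(nrow(A))
  for (v in seq_len(nrow(A))) {
    if (k[v] < 2) next
    nbv <- which(A[v, ] > 0)
    eN <- sum(A[nbv, nbv]) / 2
    cc[v] <- 2 * eN / (k[v] * (k[v] - 1))
  }
  setNames(cc, rownames(A))
}

#' Global efficiency per node
#'
#' \code{E_glob(v) = mean over u != v of 1 / d(v, u)}, with unreachable
#' nodes contributing zero; an integration measure (the whole-network
#' global efficiency is the mean over nodes, see
#' \code{\link{wholeGlobalEfficiency}}).
#'
#' @inheritParams betweennessCentrality
#' @return named numeric vector in [0, 1].
#' @export
globalEfficiencyNode <- function(graph) {
  A <- asAdjacency(graph)
  n <- nrow(A)
  if (n < 2) return(setNames(numeric(n), rownames(A)))
  nb <- .neighborList(A)
  eg <- vapply(seq_len(n), function(v) {
    d <- .bfsDist(nb, n, v)[-v]
    sum(1 / d[is.finite(d)]) / (n - 1)
  }, 0.0)
  setNames(eg, rownames(A))
}

#' @rdname globalEfficiencyNode
#' @export
wholeGlobalEfficiency <- function(graph) {
  mean(globalEfficiencyNode(graph))
}

#' Local efficiency per node
#'
#' The whole-network global efficiency of the subgraph induced by a
#' node's neighbors (the node itself excluded); zero for degree < 2.
#' A segregation measure closely related to the clustering coefficient.
#'
#' @inheritParams betweennessCentrality
#' @return named numeric vector in [0, 1].
#' @export
localEfficiency <- function(graph) {
  A <- asAdjacency(graph)
  k <- rowSums(A)
  le <- numeric(nrow(A))
  for (v in seq_len(nrow(A))) {
    if (k[v] < 2) next
    nbv <- which(A[v, ] > 0)
    le[v] <- mean(globalEfficiencyNode(A[nbv, nbv, drop = FALSE]))
  }
  setNames(le, rownames(A))
}

#' Connection density
#'
#' Per node, the realized fraction of possible edges:
#' \code{k_v / (N - 1)}; for the whole network,
#' \code{2 |E| / (N (N - 1))} (which equals the mean of the node
#' densities).
#'
#' @inheritParams betweennessCentrality
#' @return \code{nodeDensity}: named numeric vector;
#'   \code{wholeDensity}: scalar.
#' @export
nodeDensity <- function(graph) {
  A <- asAdjacency(graph)
  if (nrow(A) < 2) stopf("density needs at least 2 nodes")
  setNames(rowSums(A) / (nrow(A) - 1), rownames(A))
}

#' @rdname nodeDensity
#' @export
wholeDensity <- function(graph) {
  A <- asAdjacency(graph)
  if (nrow(A) < 2) stopf("density needs at least 2 nodes")
  sum(A) / (nrow(A) * (nrow(A) - 1))
}

#' Newman modularity of a partition
#'
#' \code{Q = sum_c [ in_c / 2m - resolution * (deg_c / 2m)^2 ]} over
#' communities c, where \code{in_c} counts internal edge endpoints and
#' \code{deg_c} the total degree of community c. Defined as 0 for an
#' edgeless graph.
#'
#' @inheritParams betweennessCentrality
#' @param membership integer community id per node.
#' @param resolution resolution parameter (1 = standard modularity).
#' @return scalar Q (at most 1).
#' @export
modularityQ <- function(graph, membership, resolution = 1) {
  A <- asAdjacency(graph)
  m2 <- sum(A)
  if (m2 == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    inC <- membership == c
    q <- q + sum(A[inC, inC]) / m2 -
      resolution * (sum(deg[inC]) / m2)^2
  }
  q
}

## One Louvain local-move phase on a weighted graph W (symmetric,
## self-loops on the diagonal). Sweeps nodes in seeded random order,
## moving each to the neighboring community with the largest positive
## modularity gain; ties keep the current community.
.louvainPhase <- function(W, resolution) {
  n <- nrow(W)
  k <- rowSums(W)
  m2 <- sum(W)
  memb <- seq_len(n)
  if (m2 == 0) return(list(membership = memb, moved = FALSE))
  ctot <- k
  movedAny <- FALSE
  ord <- sample.int(n)
  repeat {
    moved <- 0L
    for (i in ord) {
      ci <- memb[i]
      ctot[ci] <- ctot[ci] - k[i]
      wi <- W[i, ]; wi[i] <- 0
      nbc <- unique(memb[wi > 0])
      cand <- unique(c(ci, nbc))      # current community first: wins ties
      kin <- vapply(cand, function(cc) sum(wi[memb == cc]), 0.0)
      gain <- kin - resolution * k[i] * ctot[cand] / m2
      best <- cand[which.max(gain)]
      if (best != ci) {
        moved <- moved + 1L
        movedAny <- TRUE
      }
      memb[i] <- best
      ctot[best] <- ctot[best] + k[i]
    }
    if (moved == 0L) break
  }
  list(membership = memb, moved = movedAny)
}

.louvainOnce <- function(A, resolution) {
  W <- A * 1.0
  comm <- seq_len(nrow(A))   # original node -> current supernode
  repeat {
    ph <- .louvainPhase(W, resolution)
    if (!ph$moved) break
    newm <- match(ph$membership, unique(ph$membership))
    comm <- newm[comm]
    K <- max(newm)
    M <- matrix(0, nrow(W), K)
    M[cbind(seq_len(nrow(W)), newm)] <- 1
    W <- t(M) %*% W %*% M
    if (K == 1L) break
  }
  match(comm, unique(comm))
}

#' Louvain community detection
#'
#' Greedy modularity optimization: repeated local node moves (sweep
#' order shuffled under \code{seed}) followed by community aggregation,
#' until no gain remains. Isolated nodes end up as singleton
#' communities; an edgeless graph yields the all-singleton partition
#' with Q = 0. With \code{restarts > 1} the best-Q partition over
#' independently seeded runs is kept.
#'
#' @inheritParams betweennessCentrality
#' @param seed integer seed for the sweep order (and restarts).
#' @param resolution resolution parameter passed to the modularity
#'   gain.
#' @param restarts independent runs to take the best of.
#' @return list with \code{membership} (named integer vector, ids
#'   1..K) and \code{Q} (its modularity, recomputable via
#'   \code{\link{modularityQ}}).
#' @export
#' @examples
#' A <- matrix(0, 6, 6)
#' for (p in list(c(1,2), c(2,3), c(1,3), c(4,5), c(5,6), c(4,6)))
#'   A[p[1], p[2]] <- A[p[2], p[1]] <- 1
#' louvainCommunities(A, seed = 1)$Q  # two triangles: 0.5
louvainCommunities <- function(graph, seed = NULL, resolution = 1,
                               restarts = 1) {
  A <- asAdjacency(graph)
  best <- NULL
  for (r in seq_len(restarts)) {
    runSeed <- if (is.null(seed)) NULL else seed + (r - 1L)
    memb <- withSeed(runSeed, .louvainOnce(A, resolution))
    q <- modularityQ(A, memb, resolution)
    if (is.null(best) || q > best$Q) {
      best <- list(membership = setNames(memb, rownames(A)), Q = q)
    }
  }
  best
}

#' Hub nodes by the 1.5-SD betweenness rule
#'
#' Flags nodes whose betweenness centrality exceeds the graph mean by
#' more than 1.5 sample standard deviations. A zero-SD profile (all
#' values equal) yields no hubs.
#'
#' @param bc named betweenness vector (from
#'   \code{\link{betweennessCentrality}}).
#' @return character vector of hub node names.
#' @export
hubNodes <- function(bc) {
  if (length(bc) < 2) stopf("need at least 2 nodes")
  s <- sd(bc)
  if (is.na(s) || s == 0) return(character(0))
  names(bc)[bc > mean(bc) + 1.5 * s]
}

#' All node-level metrics of a graph
#'
#' One call computing the full per-node metric set: degree, betweenness
#' centrality, clustering coefficient, local and global efficiency,
#' connection density, Louvain community and hub flag.
#'
#' @inheritParams louvainCommunities
#' @return data.frame with one row per node (columns \code{node},
#'   \code{degree}, \code{betweenness}, \code{clustering},
#'   \code{local_efficiency}, \code{global_efficiency}, \code{density},
#'   \code{community}, \code{hub}); attribute \code{"Q"} holds the
#'   partition modularity, attribute \code{"group"} the graph's group.
#' @export
nodeMetrics <- function(graph, seed = NULL, resolution = 1, restarts = 1) {
  A <- asAdjacency(graph)
  bc <- betweennessCentrality(A)
  part <- louvainCommunities(A, seed = seed, resolution = resolution,
                             restarts = restarts)
  out <- data.frame(
    node = rownames(A),
    degree = unname(rowSums(A)),
    betweenness = unname(bc),
    clustering = unname(clusteringCoefficient(A)),
    local_efficiency = unname(localEfficiency(A)),
    global_efficiency = unname(globalEfficiencyNode(A)),
    density = unname(nodeDensity(A)),
    community = unname(part$membership),
    hub = rownames(A) %in% hubNodes(bc),
    stringsAsFactors = FALSE
  )
  attr(out, "Q") <- part$Q
  attr(out, "group") <- if (is(graph, "CognitiveGraph")) graph@group
  out
}
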