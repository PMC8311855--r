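## Independent brute-force oracles. These deliberately avoid the
## package's BFS/Brandes/Louvain code paths: distances come from
## adjacency-matrix powers, shortest paths from explicit enumeration,
## and maximal modularity from exhaustive search over all partitions.

randomGraph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  idx <- which(upper.tri(A))
  on <- idx[runif(length(idx)) < p]
  A[on] <- 1
  A <- A + t(A)
  rownames(A) <- colnames(A) <- paste0("n", seq_len(n))
  A
}

## Geodesic distances via matrix powers: d(u,v) = smallest k with
## (A^k)[u,v] > 0.
oracleDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  Ak <- diag(n)
  for (k in seq_len(n - 1)) {
    Ak <- Ak %*% A
    newly <- (Ak > 0) & !is.finite(D)
    D[newly] <- k
  }
  D
}

## All shortest s-t paths by recursive predecessor walking.
enumShortestPaths <- function(A, D, s, t) {
  if (s == t) return(list(s))
  preds <- which(A[t, ] > 0 & D[s, ] == D[s, t] - 1)
  out <- list()
  for (u in preds) {
    for (p in enumShortestPaths(A, D, s, u)) {
      out[[length(out) + 1L]] <- c(p, t)
    }
  }
  out
}

oracleBetweenness <- function(A) {
  n <- nrow(A)
  D <- oracleDistances(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(D[s, t])) next
      paths <- enumShortestPaths(A, D, s, t)
      mid <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(mid)) bc <- bc + tabulate(mid, n) / length(paths)
    }
  }
  bc
}

oracleGlobalEfficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(numeric(n))
  D <- oracleDistances(A)
  vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)]) / (n - 1)
  }, 0.0)
}

oracleLocalEfficiency <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    mean(oracleGlobalEfficiency(A[nb, nb, drop = FALSE]))
  }, 0.0)
}

## All set partitions of n elements as restricted-growth strings
## (rows = partitions), built iteratively and cached per n.
.partitionCache <- new.env(parent = emptyenv())
allPartitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partitionCache[[key]])) return(.partitionCache[[key]])
  P <- matrix(1L, 1, 1)
  for (i in seq_len(n)[-1]) {
    k <- apply(P, 1, max)
    P <- do.call(rbind, lapply(seq_len(nrow(P)), function(r) {
      cbind(matrix(P[r, ], k[r] + 1L, i - 1L, byrow = TRUE),
            seq_len(k[r] + 1L))
    }))
  }
  .partitionCache[[key]] <- P
  P
}

## Exhaustive maximal Newman modularity over every partition.
oracleQmax <- function(A) {
  n <- nrow(A)
  P <- allPartitions(n)
  el <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(el)
  if (m == 0) return(0)
  deg <- rowSums(A)
  m2 <- 2 * m
  inFrac <- rowSums(P[, el[, 1], drop = FALSE] ==
                      P[, el[, 2], drop = FALSE]) / m
  degTerm <- numeric(nrow(P))
  for (c in seq_len(n)) {
    degTerm <- degTerm + ((P == c) %*% deg / m2)^2
  }
  max(inFrac - degTerm)
}

## Independent modularity recomputation from an edge list (different
## code path from cognet::modularityQ's block sums).
oracleModularity <- function(A, membership) {
  el <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(el)
  if (m == 0) return(0)
  deg <- rowSums(A)
  q <- sum(membership[el[, 1]] == membership[el[, 2]]) / m
  for (c in unique(membership)) {
    q <- q - (sum(deg[membership == c]) / (2 * m))^2
  }
  q
}

## Two partitions equal up to label permutation?
samePartition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(a, b, function(x) length(unique(x))) == 1) &&
    all(tapply(b, a, function(x) length(unique(x))) == 1)
}

## Exhaustive Mann-Whitney two-tailed p by enumerating all assignments
## of pooled ranks to the first sample.
oracleMannWhitney <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  Us <- apply(combn(m + n, m), 2,
              function(ix) sum(r[ix]) - m * (m + 1) / 2)
  pLe <- mean(Us <= uObs)
  pGe <- mean(Us >= uObs)
  list(U = uObs, p = min(1, 2 * min(pLe, pGe)))
}

## Partial Spearman by a deliberately different route: lm() fits on
## ranked data and cor.
oraclePartialSpearman <- function(x, y, covs) {
  rx <- rank(x); ry <- rank(y)
  rc <- apply(as.matrix(covs), 2, rank)
  ex <- resid(lm(rx ~ rc))
  ey <- resid(lm(ry ~ rc))
  cor(ex, ey)
}
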