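## Rank-then-residualize machinery behind the partial Spearman network.

## Residualize the average ranks of v on an intercept plus the average
## ranks of the covariate columns. Returns residuals (exact zero-mean).
.rankResiduals <- function(v, covRanks) {
  rv <- rankAvg(v)
  if (is.null(covRanks) || ncol(covRanks) == 0L) {
    return(rv - mean(rv))
  }
  X <- cbind(1, covRanks)
  qr.resid(qr(X), rv)
}

#' Partial Spearman correlation
#'
#' The nonparametric partial correlation used for network formation:
#' \code{x}, \code{y} and each covariate are rank-transformed (average
#' ranks for ties), the ranks of \code{x} and \code{y} are each linearly
#' regressed on the ranked covariates (plus intercept), and the Pearson
#' correlation of the two residual vectors is returned. The analytic
#' two-tailed p-value comes from
#' \code{t = rho * sqrt((n - 2 - k) / (1 - rho^2))} on \code{n - 2 - k}
#' degrees of freedom, with \code{k} covariates. Complete cases across
#' \code{x}, \code{y} and the covariates are used (pairwise-listwise
#' deletion).
#'
#' @param x,y numeric score vectors of equal length.
#' @param covariates optional numeric matrix/data.frame of covariate
#'   columns (e.g. age and education), same number of rows.
#' @return list with \code{rho}, \code{p} (analytic, two-tailed) and
#'   \code{n} (complete cases used).
#' @export
#' @examples
#' partialSpearman(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
partialSpearman <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(x)) {
      stopf("covariates must have one row per observation")
    }
  }
  cc <- if (is.null(covariates)) {
    complete.cases(x, y)
  } else {
    complete.cases(x, y, covariates)
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- sum(cc)
  if (n < k + 3) stopf("insufficient complete cases (n = %d, need >= %d)",
                       n, k + 3)
  xs <- x[cc]; ys <- y[cc]
  if (length(unique(xs)) < 2 || length(unique(ys)) < 2) {
    stopf("constant variable on complete cases")
  }
  covRanks <- if (k > 0) {
    apply(covariates[cc, , drop = FALSE], 2, rankAvg)
  }
  ex <- .rankResiduals(xs, covRanks)
  ey <- .rankResiduals(ys, covRanks)
  rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  rho <- max(-1, min(1, rho))
  df <- n - 2 - k
  p <- if (abs(rho) >= 1) 0 else {
    2 * pt(-abs(rho * sqrt(df / (1 - rho^2))), df)
  }
  list(rho = rho, p = p, n = n)
}

#' Permutation p-value for a partial Spearman correlation
#'
#' Residualizes ranks exactly as \code{\link{partialSpearman}}, then
#' permutes one residual vector \code{nPerm} times — re-residualizing
#' each permuted vector on the covariate ranks (Freedman-Lane on
#' ranks) — and compares absolute permuted correlations with the
#' observed one. The p-value uses the add-one correction
#' \code{p = (1 + #(|rho_perm| >= |rho_obs|)) / (nPerm + 1)}, so the
#' smallest attainable p is \code{1 / (nPerm + 1)}. Permuting residuals
#' (rather than raw scores) keeps the covariate structure of the
#' unpermuted variable intact, and the re-residualization keeps the
#' permutation null on the same residual subspace as the observed
#' statistic.
#'
#' @inheritParams partialSpearman
#' @param nPerm number of randomizations (at least 100; 5000 is the
#'   conventional validation run).
#' @param seed integer seed; fixed seed implies identical p.
#' @return permutation p-value (two-sided).
#' @export
permutationP <- function(x, y, covariates = NULL, nPerm = 5000,
                         seed = NULL) {
  if (nPerm < 100) stopf("nPerm < 100 is uninformative")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  cc <- if (is.null(covariates)) {
    complete.cases(x, y)
  } else {
    complete.cases(x, y, covariates)
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- sum(cc)
  if (n < k + 3) stopf("insufficient complete cases (n = %d)", n)
  covRanks <- if (k > 0) {
    apply(covariates[cc, , drop = FALSE], 2, rankAvg)
  }
  ex <- .rankResiduals(x[cc], covRanks)
  ey <- .rankResiduals(y[cc], covRanks)
  nx <- sqrt(sum(ex^2)); ny <- sqrt(sum(ey^2))
  if (nx == 0 || ny == 0) stopf("constant variable on complete cases")
  rhoObs <- abs(sum(ex * ey) / (nx * ny))
  withSeed(seed, {
    EY <- matrix(ey[vapply(seq_len(nPerm),
                           function(i) sample.int(n), integer(n))],
                 nrow = n)
    ## ex is orthogonal to the covariate space, so re-residualizing the
    ## permuted vector leaves the numerator untouched and only shrinks
    ## its norm by the part falling back into that space.
    num <- colSums(ex * EY)
    denom2 <- if (k > 0) {
      Qm <- qr.Q(qr(cbind(1, covRanks)))
      ny^2 - colSums(crossprod(Qm, EY)^2)
    } else {
      rep(ny^2, nPerm)
    }
    rhoPerm <- abs(num) / (nx * sqrt(pmax(denom2, 1e-24)))
    (1 + sum(rhoPerm >= rhoObs - 1e-12)) / (nPerm + 1)
  })
}

#' Edge statistics for one group
#'
#' Computes the partial Spearman correlation, analytic p and
#' complete-case count for every unordered pair of tests with data in
#' the group, controlling for the given subject covariates. Pairs whose
#' analytic p falls strictly inside the validation band (default
#' 0.01 < p < 0.1) are additionally checked with a seeded permutation
#' test. Tests whose column is entirely missing are dropped from the
#' node set (so a group lacking both Prose Memory measures yields 14
#' nodes and 91 candidate edges). Pairs that fail (insufficient n,
#' constant scores) are skipped and recorded in
#' \code{attr(result, "skipped")}.
#'
#' @param groupCohort a (typically z-scored)
#'   \code{\linkS4class{CognitiveCohort}} restricted to one group.
#' @param covariates colData columns to partial out (default age and
#'   education).
#' @param validateBand numeric length-2: the open p-interval in which
#'   permutation validation runs.
#' @param nPerm permutations for in-band pairs; 0 disables validation.
#' @param seed integer seed for the permutation stream.
#' @return data.frame with one row per pair: \code{test_a},
#'   \code{test_b}, \code{rho}, \code{p_analytic}, \code{p_permutation}
#'   (NA outside the band), \code{n_used}. Attributes: \code{tests}
#'   (node set), \code{group}, \code{covariates}, \code{skipped}.
#' @export
buildEdgeStats <- function(groupCohort,
                           covariates = c("age", "education"),
                           validateBand = c(0.01, 0.1),
                           nPerm = 0, seed = NULL) {
  S <- t(scoreMatrix(groupCohort))            # subjects x tests
  cd <- as.data.frame(SummarizedExperiment::colData(groupCohort))
  missingCov <- setdiff(covariates, names(cd))
  if (length(missingCov)) {
    stopf("covariate(s) not in colData: %s",
          paste(missingCov, collapse = ", "))
  }
  covM <- if (length(covariates)) {
    as.matrix(cd[, covariates, drop = FALSE])
  }
  tests <- colnames(S)[colSums(!is.na(S)) > 0]
  if (length(tests) < 2) stopf("need at least 2 tests with data")
  group <- paste(unique(as.character(cd$group)), collapse = "+")

  pairs <- combn(tests, 2)
  rows <- vector("list", ncol(pairs))
  skipped <- list()
  withSeed(seed, {
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      est <- tryCatch(partialSpearman(S[, a], S[, b], covM),
                      error = function(e) e)
      if (inherits(est, "error")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(test_a = a, test_b = b,
                     reason = conditionMessage(est))
        next
      }
      pPerm <- NA_real_
      if (nPerm > 0 && est$p > validateBand[1] && est$p < validateBand[2]) {
        pPerm <- permutationP(S[, a], S[, b], covM, nPerm = nPerm,
                              seed = NULL)  # inherits the seeded stream
      }
      rows[[i]] <- data.frame(
        test_a = a, test_b = b, rho = est$rho, p_analytic = est$p,
        p_permutation = pPerm, n_used = est$n,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(test_a = character(0), test_b = character(0),
                      rho = numeric(0), p_analytic = numeric(0),
                      p_permutation = numeric(0), n_used = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  attr(out, "group") <- group
  attr(out, "covariates") <- covariates
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  out
}

#' Threshold edge statistics into a binary graph
#'
#' An edge joins two tests when its p-value is strictly below
#' \code{alpha} and (by default) the correlation is positive; negative
#' significant correlations are removed in the main analysis because
#' binary graph-theory metrics are validated on positively connected
#' networks, and retained (unsigned) only in the sensitivity analysis
#' (\code{dropNegative = FALSE}). When \code{usePermutationInBand} is
#' set, pairs carrying a permutation p use it instead of the analytic p
#' for the decision.
#'
#' @param edges an edge-stats data.frame from
#'   \code{\link{buildEdgeStats}}.
#' @param alpha significance level (strict inequality), in (0, 1).
#' @param dropNegative remove negative significant correlations
#'   (default TRUE).
#' @param usePermutationInBand decide in-band edges on the permutation p
#'   (default FALSE: the permutation run is a check only).
#' @param nodes node set; defaults to \code{attr(edges, "tests")}.
#' @return A \code{\linkS4class{CognitiveGraph}}.
#' @export
thresholdToGraph <- function(edges, alpha = 0.05, dropNegative = TRUE,
                             usePermutationInBand = FALSE, nodes = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(nodes)) nodes <- attr(edges, "tests")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$test_a, edges$test_b)))
  pUse <- edges$p_analytic
  if (usePermutationInBand && nrow(edges)) {
    hasPerm <- !is.na(edges$p_permutation)
    pUse[hasPerm] <- edges$p_permutation[hasPerm]
  }
  keep <- pUse < alpha
  if (dropNegative) keep <- keep & edges$rho > 0
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (any(keep)) {
    ia <- match(edges$test_a[keep], nodes)
    ib <- match(edges$test_b[keep], nodes)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  CognitiveGraph(A,
                 group = attr(edges, "group") %||% NA_character_,
                 alpha = alpha,
                 negativePolicy = if (dropNegative) "drop" else "keep",
                 covariates = attr(edges, "covariates") %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build one group's cognitive graph end to end
#'
#' Convenience wrapper: subset the cohort to \code{group}, compute edge
#' statistics and threshold them.
#'
#' @param cohort a z-scored \code{\linkS4class{CognitiveCohort}}.
#' @param group group label.
#' @inheritParams buildEdgeStats
#' @inheritParams thresholdToGraph
#' @return A \code{\linkS4class{CognitiveGraph}}.
#' @export
buildGroupGraph <- function(cohort, group,
                            covariates = c("age", "education"),
                            alpha = 0.05, dropNegative = TRUE,
                            usePermutationInBand = FALSE,
                            validateBand = c(0.01, 0.1),
                            nPerm = 0, seed = NULL) {
  edges <- buildEdgeStats(subsetGroup(cohort, group),
                          covariates = covariates,
                          validateBand = validateBand,
                          nPerm = nPerm, seed = seed)
  thresholdToGraph(edges, alpha = alpha, dropNegative = dropNegative,
                   usePermutationInBand = usePermutationInBand)
}
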