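#' Mann-Whitney U comparison of two node-metric vectors
#'
#' Two-tailed Mann-Whitney U test between the node-level metric values
#' of two group graphs (e.g. the 16 clustering coefficients of one
#' group against another's), with Bonferroni adjustment over the stated
#' family. Exact enumeration is used for combined n <= 16 without ties,
#' otherwise the tie-corrected normal approximation. Note that node
#' metrics within one graph are not independent observations — this is
#' the conventional between-graph contrast for covariance networks, not
#' a calibrated inferential test; interpret asterisks accordingly.
#'
#' @param a,b numeric metric vectors (each at least 3 values).
#' @param measure label recorded with the result.
#' @param groupA,groupB group labels.
#' @param familySize Bonferroni family size (default 1 = no
#'   correction); always recorded so the convention is auditable.
#' @return one-row data.frame: \code{measure}, \code{group_a},
#'   \code{group_b}, \code{U}, \code{p_raw}, \code{p_adjusted},
#'   \code{family_size}, \code{significant} (adjusted p < 0.05).
#' @export
#' @examples
#' mannWhitneyMetrics(c(1, 2, 3, 4), c(3, 4, 5, 6))
mannWhitneyMetrics <- function(a, b, measure = "metric",
                               groupA = "a", groupB = "b",
                               familySize = 1) {
  if (!length(a) || !length(b)) stopf("empty sample")
  if (length(a) < 3 || length(b) < 3) {
    stopf("each sample needs at least 3 values")
  }
  exact <- (length(a) + length(b) <= 16) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact)
  )
  pAdj <- min(1, wt$p.value * familySize)
  data.frame(
    measure = measure, group_a = groupA, group_b = groupB,
    U = unname(wt$statistic), p_raw = wt$p.value, p_adjusted = pAdj,
    family_size = familySize, significant = pAdj < 0.05,
    stringsAsFactors = FALSE
  )
}

#' Compare all node metrics between two graphs
#'
#' Runs \code{\link{mannWhitneyMetrics}} for each metric column shared
#' by two node-metric tables. The default Bonferroni family is
#' per-metric: the number of group pairs tested on that metric
#' (\code{familySize}).
#'
#' @param metricsA,metricsB node-metric data.frames from
#'   \code{\link{nodeMetrics}}.
#' @param metrics metric columns to compare.
#' @param groupA,groupB labels (default from the tables' group
#'   attribute).
#' @param familySize Bonferroni family size applied to every metric.
#' @return data.frame with one row per metric.
#' @export
compareMetrics <- function(metricsA, metricsB,
                           metrics = c("betweenness", "clustering",
                                       "local_efficiency",
                                       "global_efficiency", "density"),
                           groupA = NULL, groupB = NULL,
                           familySize = 1) {
  if (is.null(groupA)) groupA <- attr(metricsA, "group") %||% "a"
  if (is.null(groupB)) groupB <- attr(metricsB, "group") %||% "b"
  do.call(rbind, lapply(metrics, function(m) {
    mannWhitneyMetrics(metricsA[[m]], metricsB[[m]], measure = m,
                       groupA = groupA, groupB = groupB,
                       familySize = familySize)
  }))
}

#' Kruskal-Wallis H with Dunn post hoc tests
#'
#' Compares one test's z-scores across groups with the tie-corrected
#' Kruskal-Wallis H (df = groups - 1), followed by pairwise Dunn z
#' tests on the pooled ranks with Bonferroni correction over all group
#' pairs. All values tied across all groups gives H = 0, p = 1.
#'
#' @param cohort a z-scored \code{\linkS4class{CognitiveCohort}}.
#' @param test test (row) name to compare.
#' @param groups groups to include (default: all with data; at least 2
#'   groups with >= 3 non-missing subjects each).
#' @return list with \code{H}, \code{df}, \code{p}, and \code{dunn}, a
#'   data.frame of pairwise results (\code{group_a}, \code{group_b},
#'   \code{z}, \code{p_raw}, \code{p_adjusted}, \code{family_size},
#'   \code{significant}).
#' @export
kruskalDunn <- function(cohort, test, groups = NULL) {
  S <- scoreMatrix(cohort)
  if (!test %in% rownames(S)) stopf("unknown test '%s'", test)
  g <- as.character(SummarizedExperiment::colData(cohort)$group)
  x <- S[test, ]
  ok <- !is.na(x)
  x <- x[ok]; g <- g[ok]
  if (is.null(groups)) groups <- unique(g)
  keep <- g %in% groups
  x <- x[keep]; g <- factor(g[keep], levels = groups)
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 3)) {
    stopf("need >= 2 groups with >= 3 subjects each")
  }
  if (length(unique(x)) == 1L) {
    kw <- list(H = 0, df = length(groups) - 1L, p = 1)
  } else {
    kt <- kruskal.test(x, g)
    kw <- list(H = unname(kt$statistic), df = unname(kt$parameter),
               p = kt$p.value)
  }

  ## Dunn z on pooled average ranks with tie correction
  N <- length(x)
  r <- rankAvg(x)
  meanRank <- tapply(r, g, mean)
  tiesTab <- table(x)
  tieCorr <- sum(tiesTab^3 - tiesTab) / (12 * (N - 1))
  pairs <- combn(levels(g), 2)
  fam <- ncol(pairs)
  rows <- lapply(seq_len(fam), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                 (1 / sizes[[ga]] + 1 / sizes[[gb]]))
    zval <- if (se == 0) 0 else (meanRank[[ga]] - meanRank[[gb]]) / se
    pRaw <- 2 * pnorm(-abs(zval))
    pAdj <- min(1, pRaw * fam)
    data.frame(group_a = ga, group_b = gb, z = zval, p_raw = pRaw,
               p_adjusted = pAdj, family_size = fam,
               significant = pAdj < 0.05, stringsAsFactors = FALSE)
  })
  c(kw, list(dunn = do.call(rbind, rows)))
}

#' Chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction, for categorical
#' demographics (e.g. gender by group), df = (rows - 1)(cols - 1).
#'
#' @param counts matrix of nonnegative counts.
#' @return one-row data.frame: \code{statistic}, \code{df},
#'   \code{p_raw}.
#' @export
#' @examples
#' chiSquareCategorical(rbind(c(31, 37), c(44, 38)))
chiSquareCategorical <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stopf("zero marginal in contingency table")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  data.frame(statistic = unname(ct$statistic),
             df = unname(ct$parameter),
             p_raw = ct$p.value)
}
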