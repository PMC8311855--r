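#' @import methods
#' @importFrom stats complete.cases cor pt sd setNames aggregate chisq.test
#'   kruskal.test wilcox.test pnorm runif rnorm qnorm p.adjust
#' @importFrom utils combn read.csv write.csv packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.COGNITIVE_DOMAINS <- c("memory", "semantic", "abstract", "executive")

#' Cognitive test battery metadata
#'
#' A \code{TestBattery} records, for each test in a neuropsychological
#' battery, whether a higher raw score indicates better performance and
#' which cognitive domains (memory, semantic processing, abstract
#' reasoning, executive functioning) the test is assigned to. A test may
#' belong to several domains or to none.
#'
#' @slot tests character vector of unique test names.
#' @slot higherIsBetter named logical, one entry per test; \code{FALSE}
#'   for time/error measures where a larger raw score means worse
#'   performance.
#' @slot domains named list, one character vector per test, each a subset
#'   of \code{c("memory", "semantic", "abstract", "executive")};
#'   \code{character(0)} means the test feeds no domain profile.
#'
#' @seealso \code{\link{canonicalBattery}}, \code{\link{syntheticBattery}}
#' @exportClass TestBattery
setClass("TestBattery",
  representation(
    tests = "character",
    higherIsBetter = "logical",
    domains = "list"
  )
)

setValidity("TestBattery", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@tests)) msgs <- c(msgs, "test names must be unique")
  if (length(object@higherIsBetter) != length(object@tests) ||
      length(object@domains) != length(object@tests)) {
    msgs <- c(msgs, "higherIsBetter and domains must have one entry per test")
  }
  bad <- setdiff(unlist(object@domains), .COGNITIVE_DOMAINS)
  if (length(bad)) {
    msgs <- c(msgs, paste0("unknown domain(s): ", paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TestBattery
#'
#' @param tests character vector of test names.
#' @param higherIsBetter logical vector (recycled if length 1): does a
#'   higher raw score mean better performance?
#' @param domains list of character vectors (one per test) naming the
#'   domains each test belongs to; entries must be drawn from
#'   \code{c("memory", "semantic", "abstract", "executive")}.
#' @return A \code{\linkS4class{TestBattery}}.
#' @export
#' @examples
#' TestBattery(c("recall", "naming"),
#'             higherIsBetter = TRUE,
#'             domains = list("memory", "semantic"))
TestBattery <- function(tests, higherIsBetter = TRUE, domains = NULL) {
  tests <- as.character(tests)
  if (length(higherIsBetter) == 1L) {
    higherIsBetter <- rep(higherIsBetter, length(tests))
  }
  if (is.null(domains)) domains <- rep(list(character(0)), length(tests))
  domains <- lapply(domains, as.character)
  names(higherIsBetter) <- tests
  names(domains) <- tests
  new("TestBattery", tests = tests, higherIsBetter = higherIsBetter,
      domains = domains)
}

#' Subject-by-test cognitive cohort
#'
#' \code{CognitiveCohort} extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}}: the
#' \code{"scores"} assay holds one row per cognitive test and one column
#' per subject; \code{colData} carries the subject covariates
#' (\code{group}, \code{age}, \code{education} and, when available,
#' \code{mmse}). The governing \code{\linkS4class{TestBattery}} is stored
#' in \code{metadata(x)$battery}. Missing scores are \code{NA}, never a
#' sentinel value.
#'
#' @seealso \code{\link{CognitiveCohort}}, \code{\link{generateCohort}},
#'   \code{\link{readCohort}}
#' @exportClass CognitiveCohort
setClass("CognitiveCohort", contains = "SummarizedExperiment")

setValidity("CognitiveCohort", function(object) {
  msgs <- character(0)
  if (!"scores" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'scores' is required")
  }
  needed <- c("group", "age", "education")
  missing <- setdiff(needed, colnames(SummarizedExperiment::colData(object)))
  if (length(missing)) {
    msgs <- c(msgs, paste0("colData must contain: ",
                           paste(missing, collapse = ", ")))
  }
  bat <- S4Vectors::metadata(object)$battery
  if (!is.null(bat)) {
    if (!is(bat, "TestBattery")) {
      msgs <- c(msgs, "metadata battery must be a TestBattery")
    } else if (!all(rownames(object) %in% bat@tests)) {
      msgs <- c(msgs, "every row (test) must appear in the battery")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Binary cognitive graph
#'
#' An undirected, unweighted graph over cognitive tests: the thresholded
#' adjacency matrix of one group's partial-correlation network, together
#' with the provenance of the thresholding decision.
#'
#' @slot adjacency square symmetric 0/1 matrix with zero diagonal;
#'   dimnames are the test (node) labels.
#' @slot group label of the cohort group the graph belongs to.
#' @slot alpha significance level used at thresholding.
#' @slot negativePolicy \code{"drop"} (negative correlations removed, the
#'   default analysis) or \code{"keep"} (sensitivity analysis).
#' @slot covariates covariate labels partialled out of the correlations.
#'
#' @seealso \code{\link{thresholdToGraph}}, \code{\link{nodeMetrics}}
#' @exportClass CognitiveGraph
setClass("CognitiveGraph",
  representation(
    adjacency = "matrix",
    group = "character",
    alpha = "numeric",
    negativePolicy = "character",
    covariates = "character"
  )
)

setValidity("CognitiveGraph", function(object) {
  A <- object@adjacency
  msgs <- character(0)
  if (!isBinaryAdjacency(A)) {
    msgs <- c(msgs,
      "adjacency must be a square symmetric 0/1 matrix with zero diagonal")
  }
  if (is.null(rownames(A)) || is.null(colnames(A)) ||
      !identical(rownames(A), colnames(A))) {
    msgs <- c(msgs, "adjacency needs identical row/column node labels")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CognitiveGraph from an adjacency matrix
#'
#' @param adjacency square symmetric 0/1 matrix with labelled dimnames.
#' @param group,alpha,negativePolicy,covariates provenance fields; see
#'   \code{\linkS4class{CognitiveGraph}}.
#' @return A \code{\linkS4class{CognitiveGraph}}.
#' @export
CognitiveGraph <- function(adjacency, group = NA_character_, alpha = NA_real_,
                           negativePolicy = "drop",
                           covariates = character(0)) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (is.null(rownames(adjacency))) {
    rownames(adjacency) <- colnames(adjacency) <-
      paste0("node", seq_len(nrow(adjacency)))
  }
  new("CognitiveGraph", adjacency = adjacency, group = as.character(group),
      alpha = alpha, negativePolicy = negativePolicy,
      covariates = as.character(covariates))
}
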