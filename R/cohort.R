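#' Construct a CognitiveCohort
#'
#' @param scores numeric matrix, tests (rows) x subjects (columns);
#'   \code{NA} marks a missing score.
#' @param subjects data.frame with one row per subject and at least
#'   columns \code{group}, \code{age}, \code{education}; \code{mmse} and
#'   further covariates are carried along.
#' @param battery the governing \code{\linkS4class{TestBattery}}; when
#'   supplied, the score rows must all be battery tests.
#' @return A \code{\linkS4class{CognitiveCohort}}.
#' @export
#' @examples
#' b <- syntheticBattery(2, 2)
#' m <- matrix(rnorm(20), nrow = 4, dimnames = list(testNames(b), NULL))
#' subj <- data.frame(group = "g1", age = 30:34, education = 12)
#' CognitiveCohort(m, subj, b)
CognitiveCohort <- function(scores, subjects, battery = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) stopf("score rows must be named by test")
  subjects <- as.data.frame(subjects)
  if (nrow(subjects) != ncol(scores)) {
    stopf("subjects (%d rows) must match score columns (%d)",
          nrow(subjects), ncol(scores))
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- if (!is.null(subjects$subject)) {
      as.character(subjects$subject)
    } else {
      sprintf("S%03d", seq_len(ncol(scores)))
    }
  }
  md <- list()
  if (!is.null(battery)) md$battery <- battery
  cd <- S4Vectors::DataFrame(subjects)
  rownames(cd) <- colnames(scores)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scores = scores),
    colData = cd,
    metadata = md
  )
  new("CognitiveCohort", se)
}

#' Accessors for CognitiveCohort
#'
#' \code{scoreMatrix} returns the tests-by-subjects score assay;
#' \code{batteryOf} the governing battery; \code{groupNames} the group
#' labels present; \code{subsetGroup} the cohort restricted to one group.
#'
#' @param x a \code{\linkS4class{CognitiveCohort}}.
#' @param group a group label.
#' @name CognitiveCohort-accessors
NULL

#' @rdname CognitiveCohort-accessors
setMethod("scoreMatrix", "CognitiveCohort", function(x) {
  SummarizedExperiment::assay(x, "scores")
})

#' @rdname CognitiveCohort-accessors
setMethod("batteryOf", "CognitiveCohort", function(x) {
  S4Vectors::metadata(x)$battery
})

#' @rdname CognitiveCohort-accessors
setMethod("groupNames", "CognitiveCohort", function(x) {
  unique(as.character(SummarizedExperiment::colData(x)$group))
})

#' @rdname CognitiveCohort-accessors
setMethod("subsetGroup", "CognitiveCohort", function(x, group) {
  keep <- as.character(SummarizedExperiment::colData(x)$group) == group
  if (!any(keep)) stopf("no subjects in group '%s'", group)
  x[, keep]
})

setMethod("show", "CognitiveCohort", function(object) {
  g <- table(as.character(SummarizedExperiment::colData(object)$group))
  cat("CognitiveCohort:", nrow(object), "tests x", ncol(object),
      "subjects\n")
  cat("  groups:",
      paste(sprintf("%s (n=%d)", names(g), as.integer(g)), collapse = ", "),
      "\n")
  if (isTRUE(S4Vectors::metadata(object)$standardized)) {
    cat("  scores: z-standardized (",
        S4Vectors::metadata(object)$norm_source, ")\n", sep = "")
  } else {
    cat("  scores: raw\n")
  }
})

#' Read / write a cohort score table
#'
#' The on-disk interchange format is CSV with one row per subject:
#' columns \code{subject}, \code{group}, \code{age}, \code{education},
#' optionally \code{mmse}, then one column per test. Empty fields are
#' missing scores.
#'
#' @param file path to a cohort CSV.
#' @param battery optional \code{\linkS4class{TestBattery}}; when given,
#'   test columns are taken from it (and must all be present), otherwise
#'   every non-covariate column is treated as a test.
#' @param cohort a \code{\linkS4class{CognitiveCohort}} to serialize.
#' @return \code{readCohort} returns a \code{CognitiveCohort};
#'   \code{writeCohort} returns \code{file} invisibly.
#' @export
readCohort <- function(file, battery = NULL) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  covCols <- intersect(c("subject", "group", "age", "education", "mmse"),
                       names(df))
  if (!all(c("group", "age", "education") %in% covCols)) {
    stopf("cohort file needs group, age and education columns")
  }
  testCols <- if (!is.null(battery)) {
    missing <- setdiff(testNames(battery), names(df))
    if (length(missing)) {
      stopf("cohort file lacks battery tests: %s",
            paste(missing, collapse = ", "))
    }
    testNames(battery)
  } else {
    setdiff(names(df), covCols)
  }
  scores <- t(as.matrix(df[, testCols, drop = FALSE]))
  storage.mode(scores) <- "double"
  CognitiveCohort(scores, df[, covCols, drop = FALSE], battery)
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, file) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  keep <- intersect(c("subject", "group", "age", "education", "mmse"),
                    names(cd))
  out <- cbind(cd[, keep, drop = FALSE],
               as.data.frame(t(scoreMatrix(cohort))))
  write.csv(out, file, row.names = FALSE, na = "")
  invisible(file)
}
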