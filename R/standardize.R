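#' Per-test norms from a reference sample
#'
#' Computes, for every test with data, the mean and sample standard
#' deviation (n - 1 denominator) over non-missing reference scores —
#' the ingredients of norm-referenced z-scores.
#'
#' @param reference a \code{\linkS4class{CognitiveCohort}} holding the
#'   reference sample (e.g. all healthy subjects, one age group, or the
#'   matched control group).
#' @param provenance label recorded with the norms.
#' @return data.frame with columns \code{test}, \code{mean}, \code{sd},
#'   \code{n}, \code{provenance}. Tests with fewer than 2 non-missing
#'   values are dropped; a zero-variance test is an error (its z-scores
#'   would be undefined).
#' @export
#' @examples
#' coh <- generateCohort(groupSpec("g", 30), canonicalBattery(), seed = 1)
#' head(computeNorms(coh))
computeNorms <- function(reference, provenance = "reference") {
  S <- scoreMatrix(reference)
  n <- rowSums(!is.na(S))
  keep <- n >= 2
  m <- rowMeans(S, na.rm = TRUE)
  s <- apply(S, 1, sd, na.rm = TRUE)
  zv <- keep & (is.na(s) | s == 0)
  if (any(zv)) {
    stopf("zero variance in reference for test(s): %s",
          paste(rownames(S)[zv], collapse = ", "))
  }
  data.frame(
    test = rownames(S)[keep],
    mean = unname(m[keep]),
    sd = unname(s[keep]),
    n = unname(n[keep]),
    provenance = provenance,
    stringsAsFactors = FALSE
  )
}

#' Norm-reference scores to oriented z-scores
#'
#' Applies \code{z = (raw - mean) / sd} per test using the supplied
#' norms, then (by default) flips the sign of reverse-oriented tests so
#' that a higher z always means better performance. Missing scores stay
#' missing. Z-scoring is monotone per test, so within-test subject
#' ranks — and hence any downstream Spearman analysis — are unchanged.
#'
#' @param cohort a \code{\linkS4class{CognitiveCohort}} (raw scores).
#' @param norms a norms data.frame from \code{\link{computeNorms}}; it
#'   must cover every test of \code{cohort} that has any data.
#' @param orient flip reverse-oriented tests (needs a battery on the
#'   cohort or via \code{battery}).
#' @param battery battery providing orientation flags; defaults to the
#'   cohort's.
#' @return A \code{\linkS4class{CognitiveCohort}} of z-scores; metadata
#'   records the norm provenance.
#' @export
applyNorms <- function(cohort, norms, orient = TRUE, battery = NULL) {
  S <- scoreMatrix(cohort)
  present <- rownames(S)[rowSums(!is.na(S)) > 0]
  uncovered <- setdiff(present, norms$test)
  if (length(uncovered)) {
    stopf("norms do not cover test(s): %s", paste(uncovered, collapse = ", "))
  }
  idx <- match(rownames(S), norms$test)
  Z <- (S - norms$mean[idx]) / norms$sd[idx]
  if (orient) {
    if (is.null(battery)) battery <- batteryOf(cohort)
    if (is.null(battery)) {
      stopf("orientation requested but no battery available")
    }
    flip <- !isHigherBetter(battery)[rownames(Z)]
    flip[is.na(flip)] <- FALSE
    Z[flip, ] <- -Z[flip, ]
  }
  out <- cohort
  SummarizedExperiment::assay(out, "scores") <- Z
  S4Vectors::metadata(out)$standardized <- TRUE
  S4Vectors::metadata(out)$norm_source <- unique(norms$provenance)
  out
}

#' Standardize a cohort under one of three referencing schemes
#'
#' Wraps \code{\link{computeNorms}} + \code{\link{applyNorms}} with the
#' three referencing schemes a clinical network study needs:
#' \describe{
#'   \item{\code{"own-group"}}{each group is z-scored against its own
#'     mean and SD (the scheme used before building each healthy
#'     group's network; self-normed columns have mean 0, SD 1).}
#'   \item{\code{"overall"}}{every subject is z-scored against the
#'     pooled reference groups (for between-group score comparisons).}
#'   \item{\code{"matched"}}{every subject is z-scored against one
#'     designated control group (the scheme for patient groups, normed
#'     on their matched controls).}
#' }
#'
#' @param cohort a raw-score \code{\linkS4class{CognitiveCohort}}.
#' @param normSource \code{"own-group"}, \code{"overall"} or
#'   \code{"matched"}.
#' @param referenceGroups groups pooled as the reference for
#'   \code{"overall"} (default: all groups present).
#' @param matchedGroup the control group for \code{"matched"}.
#' @param orient flip reverse-oriented tests (default TRUE).
#' @return A z-scored \code{\linkS4class{CognitiveCohort}}.
#' @export
#' @examples
#' coh <- generateCohort(defaultStudyGroups()[1:2], canonicalBattery(), 1)
#' z <- standardizeCohort(coh, "own-group")
standardizeCohort <- function(cohort,
                              normSource = c("own-group", "overall",
                                             "matched"),
                              referenceGroups = NULL,
                              matchedGroup = NULL,
                              orient = TRUE) {
  normSource <- match.arg(normSource)
  battery <- batteryOf(cohort)
  if (normSource == "own-group") {
    groups <- groupNames(cohort)
    parts <- lapply(groups, function(g) {
      sub <- subsetGroup(cohort, g)
      applyNorms(sub, computeNorms(sub, provenance = paste0("own:", g)),
                 orient = orient, battery = battery)
    })
    Z <- do.call(cbind, lapply(parts, scoreMatrix))
    Z <- Z[, colnames(cohort), drop = FALSE]  # original subject order
    out <- cohort
    SummarizedExperiment::assay(out, "scores") <- Z
    S4Vectors::metadata(out)$standardized <- TRUE
    S4Vectors::metadata(out)$norm_source <- "own-group"
    return(out)
  }
  ref <- if (normSource == "overall") {
    if (is.null(referenceGroups)) referenceGroups <- groupNames(cohort)
    keep <- as.character(SummarizedExperiment::colData(cohort)$group) %in%
      referenceGroups
    cohort[, keep]
  } else {
    if (is.null(matchedGroup)) {
      stopf("normSource = 'matched' needs matchedGroup")
    }
    subsetGroup(cohort, matchedGroup)
  }
  prov <- if (normSource == "overall") "overall" else
    paste0("matched:", matchedGroup)
  applyNorms(cohort, computeNorms(ref, provenance = prov),
             orient = orient, battery = battery)
}
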