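#' Accessors for TestBattery
#'
#' \code{testNames} returns the test labels; \code{isHigherBetter} the
#' named orientation flags; \code{domainsOf} the domain set of one test;
#' \code{domainMembers} the tests assigned to one domain.
#'
#' @param x a \code{\linkS4class{TestBattery}}.
#' @param test a test name.
#' @param domain one of \code{"memory"}, \code{"semantic"},
#'   \code{"abstract"}, \code{"executive"}.
#' @name TestBattery-accessors
NULL

#' @rdname TestBattery-accessors
setMethod("testNames", "TestBattery", function(x) x@tests)

#' @rdname TestBattery-accessors
setMethod("isHigherBetter", "TestBattery", function(x) x@higherIsBetter)

#' @rdname TestBattery-accessors
setMethod("domainsOf", "TestBattery", function(x, test) {
  if (!test %in% x@tests) stopf("unknown test '%s'", test)
  x@domains[[test]]
})

#' @rdname TestBattery-accessors
setMethod("domainMembers", "TestBattery", function(x, domain) {
  domain <- match.arg(domain, .COGNITIVE_DOMAINS)
  x@tests[vapply(x@domains, function(d) domain %in% d, logical(1))]
})

setMethod("length", "TestBattery", function(x) length(x@tests))

setMethod("show", "TestBattery", function(object) {
  cat("TestBattery with", length(object@tests), "tests\n")
  for (d in .COGNITIVE_DOMAINS) {
    m <- domainMembers(object, d)
    cat(sprintf("  %-10s %s\n", paste0(d, ":"),
                if (length(m)) paste(m, collapse = ", ") else "(none)"))
  }
  rev <- object@tests[!object@higherIsBetter]
  if (length(rev)) {
    cat("  reverse-oriented:", paste(rev, collapse = ", "), "\n")
  }
})

#' The canonical 16-test neuropsychological battery
#'
#' The standard tertiary-care battery the package models: 16 tests with
#' their cognitive-domain assignments. Memory comprises Rey-Osterrieth
#' Complex Figure recall, both Prose Memory measures and Verbal Paired
#' Associates; semantic processing comprises Similarities, Category
#' Fluency and Confrontation Naming; abstract reasoning shares
#' Similarities and Category Fluency but swaps Confrontation Naming for
#' Raven's Progressive Matrices; executive functioning comprises the two
#' Stroop interference measures, Letter Fluency and backward Digit Span.
#' The remaining four tests (forward Digit Span, Digit Cancellation,
#' Rey-Osterrieth copy, Token Test) feed no domain profile. The two
#' Stroop interference scores are time/error counts, so they are flagged
#' reverse-oriented (a larger raw score is worse); edit the flags if your
#' scoring convention differs.
#'
#' @return A \code{\linkS4class{TestBattery}} of 16 tests.
#' @export
#' @examples
#' b <- canonicalBattery()
#' domainMembers(b, "memory")
canonicalBattery <- function() {
  TestBattery(
    tests = c(
      "ROCF_Recall", "ProseMemory_Immediate", "ProseMemory_Delayed",
      "VerbalPairedAssociates", "RavenMatrices", "Similarities",
      "CategoryFluency", "ConfrontationNaming", "LetterFluency",
      "Stroop_TimeInterference", "Stroop_ErrorInterference",
      "DigitSpan_Backward", "DigitSpan_Forward", "DigitCancellation",
      "ROCF_Copy", "TokenTest"
    ),
    higherIsBetter = c(
      TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
      FALSE, FALSE,      # Stroop time and error interference
      TRUE, TRUE, TRUE, TRUE, TRUE
    ),
    domains = list(
      "memory", "memory", "memory", "memory",
      "abstract",
      c("semantic", "abstract"), c("semantic", "abstract"), "semantic",
      "executive", "executive", "executive", "executive",
      character(0), character(0), character(0), character(0)
    )
  )
}

#' A synthetic battery with disjoint planted domains
#'
#' Builds a battery of \code{nDomains * testsPerDomain} tests with
#' non-overlapping domain blocks, used to study community recovery on
#' cleanly planted correlation structure.
#'
#' @param nDomains number of domains (at most 4, mapped onto memory,
#'   semantic, abstract, executive in that order).
#' @param testsPerDomain tests per domain block.
#' @return A \code{\linkS4class{TestBattery}}.
#' @export
syntheticBattery <- function(nDomains = 4, testsPerDomain = 4) {
  stopifnot(nDomains >= 1, nDomains <= 4, testsPerDomain >= 1)
  doms <- .COGNITIVE_DOMAINS[seq_len(nDomains)]
  tests <- unlist(lapply(doms, function(d) {
    paste0(d, "_t", seq_len(testsPerDomain))
  }))
  TestBattery(tests, TRUE,
              domains = as.list(rep(doms, each = testsPerDomain)))
}

#' Read / write a battery definition file
#'
#' The file format is CSV with columns \code{test},
#' \code{higher_is_better} (TRUE/FALSE) and \code{domains}
#' (semicolon-separated, empty for none), so the orientation of every
#' test is explicit and editable.
#'
#' @param file path to a battery CSV.
#' @param battery a \code{\linkS4class{TestBattery}} to serialize.
#' @return \code{readBattery} returns a \code{TestBattery};
#'   \code{writeBattery} returns \code{file} invisibly.
#' @export
readBattery <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("test", "higher_is_better", "domains")
  if (!all(need %in% names(df))) {
    stopf("battery file must have columns: %s", paste(need, collapse = ", "))
  }
  doms <- lapply(df$domains, function(s) {
    s <- trimws(strsplit(as.character(s), ";", fixed = TRUE)[[1]])
    s[nzchar(s)]
  })
  TestBattery(df$test, as.logical(df$higher_is_better), doms)
}

#' @rdname readBattery
#' @export
writeBattery <- function(battery, file) {
  df <- data.frame(
    test = battery@tests,
    higher_is_better = unname(battery@higherIsBetter),
    domains = vapply(battery@domains, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
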