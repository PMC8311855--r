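test_that("target correlation matrix follows the block definition", {
  b2 <- TestBattery(c("t1", "t2"), TRUE, list("memory", "memory"))
  expect_equal(buildTargetCorrelation(b2, 0.5, 0.1),
               matrix(c(1, 0.5, 0.5, 1), 2,
                      dimnames = list(c("t1", "t2"), c("t1", "t2"))))

  b <- canonicalBattery()
  expect_equal(buildTargetCorrelation(b, 0, 0),
               diag(1, 16) |>
                 `dimnames<-`(list(testNames(b), testNames(b))))

  R <- buildTargetCorrelation(b, 0.6, 0.2)
  # eigenvalue oracle: smallest eigenvalue nonnegative
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # shared-domain pairs get rWithin even across different domains
  expect_equal(R["Similarities", "RavenMatrices"], 0.6)    # abstract
  expect_equal(R["Similarities", "ConfrontationNaming"], 0.6) # semantic
  expect_equal(R["RavenMatrices", "ConfrontationNaming"], 0.2)
})

test_that("non-PSD targets are rejected with the offending eigenvalue", {
  # overlap chain memory-(memory,semantic)-semantic at high rWithin makes
  # [[1,.9,0],[.9,1,.9],[0,.9,1]], smallest eigenvalue 1 - .9*sqrt(2) < 0
  b <- TestBattery(c("a", "b", "c"), TRUE,
                   list("memory", c("memory", "semantic"), "semantic"))
  expect_error(buildTargetCorrelation(b, 0.9, 0),
               "not positive semi-definite.*eigenvalue")
})

test_that("cohort generation is deterministic under seed", {
  g <- defaultStudyGroups()
  c1 <- generateCohort(g, canonicalBattery(), seed = 7)
  c2 <- generateCohort(g, canonicalBattery(), seed = 7)
  expect_identical(scoreMatrix(c1), scoreMatrix(c2))
  expect_identical(
    as.data.frame(SummarizedExperiment::colData(c1)),
    as.data.frame(SummarizedExperiment::colData(c2))
  )
  c3 <- generateCohort(g, canonicalBattery(), seed = 8)
  expect_false(identical(scoreMatrix(c1), scoreMatrix(c3)))
})

test_that("missing tests are emitted as all-NA columns for the group", {
  coh <- generateCohort(defaultStudyGroups(), canonicalBattery(), seed = 1)
  young <- scoreMatrix(subsetGroup(coh, "young"))
  expect_true(all(is.na(young["ProseMemory_Immediate", ])))
  expect_true(all(is.na(young["ProseMemory_Delayed", ])))
  expect_true(all(!is.na(young["ROCF_Recall", ])))
  older <- scoreMatrix(subsetGroup(coh, "older"))
  expect_true(all(!is.na(older)))
})

test_that("independent tests yield near-zero sample correlations", {
  g <- groupSpec("g", 50, rWithin = 0, rBetween = 0,
                 marginalTransform = "none")
  coh <- generateCohort(g, canonicalBattery(), seed = 3)
  C <- cor(t(scoreMatrix(coh)), method = "spearman")
  expect_lt(max(abs(C[upper.tri(C)])), 0.35)
})

test_that("monotone skew transform leaves the Spearman structure intact", {
  b <- syntheticBattery(2, 3)
  gN <- groupSpec("g", 40, rWithin = 0.5, rBetween = 0.1,
                  marginalTransform = "none")
  gS <- groupSpec("g", 40, rWithin = 0.5, rBetween = 0.1,
                  marginalTransform = "skew")
  cN <- cor(t(scoreMatrix(generateCohort(gN, b, seed = 5))),
            method = "spearman")
  cS <- cor(t(scoreMatrix(generateCohort(gS, b, seed = 5))),
            method = "spearman")
  expect_equal(cN, cS, tolerance = 1e-12)
})

test_that("planted Spearman blocks are recovered on average", {
  # Monte-Carlo oracle: mean within-domain sample Spearman over
  # replicate seeds converges to the planted value
  b <- syntheticBattery(1, 4)
  g <- groupSpec("g", 75, rWithin = 0.6, rBetween = 0)
  means <- vapply(seq_len(200), function(s) {
    C <- cor(t(scoreMatrix(generateCohort(g, b, seed = 1000 + s))),
             method = "spearman")
    mean(C[upper.tri(C)])
  }, 0.0)
  expect_lt(abs(mean(means) - 0.6), 0.05)
})

test_that("group specs are validated", {
  expect_error(groupSpec("g", 5), "n must be >= 10")
  expect_error(groupSpec("g", 20, rWithin = 0.2, rBetween = 0.4),
               "rBetween <= rWithin")
  expect_error(
    generateCohort(list(groupSpec("a", 10), groupSpec("a", 10)),
                   canonicalBattery(), seed = 1),
    "unique"
  )
  expect_error(
    generateCohort(groupSpec("a", 10, missingTests = "NotATest"),
                   canonicalBattery(), seed = 1),
    "missingTests"
  )
})

test_that("cohort tables round-trip through the delimited format", {
  coh <- generateCohort(defaultStudyGroups()[c("young", "older")],
                        canonicalBattery(), seed = 2)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeCohort(coh, f)
  back <- readCohort(f, canonicalBattery())
  expect_equal(scoreMatrix(back), scoreMatrix(coh), tolerance = 1e-12)
  expect_equal(
    as.data.frame(SummarizedExperiment::colData(back))$age,
    as.data.frame(SummarizedExperiment::colData(coh))$age,
    tolerance = 1e-12
  )
  # missing scores travel as empty fields, not zeros
  expect_true(all(is.na(scoreMatrix(subsetGroup(back, "young"))[
    "ProseMemory_Immediate", ])))
})
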