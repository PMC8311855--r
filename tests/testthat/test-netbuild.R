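test_that("partial Spearman reduces to plain Spearman and handles identity", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(partialSpearman(x, x)$rho, 1)
  y <- c(2, 1, 4, 3, 6, 5)
  expect_equal(partialSpearman(1:6, y)$rho,
               cor(1:6, y, method = "spearman"), tolerance = 1e-12)
})

test_that("partial Spearman matches the rank-residual OLS oracle", {
  x <- 1:6
  y <- c(2, 1, 4, 3, 6, 5)
  z <- c(1, 1, 2, 2, 3, 3)
  got <- partialSpearman(x, y, cbind(z = z))
  expect_equal(got$rho, oraclePartialSpearman(x, y, cbind(z)),
               tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    xx <- rnorm(n); yy <- rnorm(n)
    cv <- cbind(rnorm(n), sample(5:20, n, TRUE))
    expect_equal(partialSpearman(xx, yy, cv)$rho,
                 oraclePartialSpearman(xx, yy, cv), tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(partialSpearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(partialSpearman(1:4, 4:1, cbind(rnorm(4), rnorm(4))),
               "insufficient complete cases")
  expect_error(permutationP(1:20, 20:1, nPerm = 50), "uninformative")
})

test_that("analytic p is calibrated under the null", {
  set.seed(31)
  p <- vapply(seq_len(2000), function(i) {
    cv <- cbind(runif(70, 18, 90), runif(70, 5, 20))
    partialSpearman(rnorm(70), rnorm(70), cv)$p
  }, 0.0)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("permutation p is deterministic, bounded below, and add-one corrected", {
  x <- rnorm(40); y <- x + rnorm(40, sd = 0.1)
  cv <- cbind(runif(40))
  p1 <- permutationP(x, y, cv, nPerm = 500, seed = 99)
  p2 <- permutationP(x, y, cv, nPerm = 500, seed = 99)
  expect_identical(p1, p2)
  # maximal statistic attains the minimal p
  expect_equal(permutationP(1:30, 1:30, nPerm = 1000, seed = 1),
               1 / 1001)
})

test_that("edge stats have C(T,2) rows and track the node set", {
  coh <- generateCohort(defaultStudyGroups(), canonicalBattery(), seed = 2)
  z <- standardizeCohort(coh, "own-group")
  e16 <- buildEdgeStats(subsetGroup(z, "older"))
  expect_equal(nrow(e16), choose(16, 2))
  expect_length(attr(e16, "tests"), 16)
  e14 <- buildEdgeStats(subsetGroup(z, "young"))
  expect_equal(nrow(e14), choose(14, 2))
  expect_length(attr(e14, "tests"), 14)
  expect_false(any(grepl("ProseMemory", attr(e14, "tests"))))
  expect_true(all(e16$n_used >= 2 + 3))
})

test_that("thresholding follows the strict alpha and negative-edge rules", {
  edges <- data.frame(
    test_a = c("a", "a", "b"), test_b = c("b", "c", "c"),
    rho = c(0.3, 0.3, -0.4),
    p_analytic = c(0.049, 0.051, 0.001),
    p_permutation = NA_real_, n_used = 70
  )
  attr(edges, "tests") <- c("a", "b", "c")
  g <- thresholdToGraph(edges, alpha = 0.05)
  A <- adjacency(g)
  expect_equal(A["a", "b"], 1)   # p = 0.049 < alpha
  expect_equal(A["a", "c"], 0)   # p = 0.051: strict inequality
  expect_equal(A["b", "c"], 0)   # negative rho dropped
  gKeep <- thresholdToGraph(edges, alpha = 0.05, dropNegative = FALSE)
  expect_equal(adjacency(gKeep)["b", "c"], 1)

  edges$p_analytic <- 1
  expect_equal(wholeDensity(thresholdToGraph(edges)), 0)
})

test_that("permutation p can replace the analytic p inside the band", {
  edges <- data.frame(
    test_a = "a", test_b = "b", rho = 0.25,
    p_analytic = 0.04, p_permutation = 0.07, n_used = 70
  )
  attr(edges, "tests") <- c("a", "b")
  expect_equal(sum(adjacency(thresholdToGraph(edges))), 2)
  expect_equal(sum(adjacency(
    thresholdToGraph(edges, usePermutationInBand = TRUE))), 0)
})

test_that("relaxing alpha never removes an edge", {
  coh <- generateCohort(groupSpec("g", 60, rWithin = 0.4, rBetween = 0.1),
                        canonicalBattery(), seed = 13)
  e <- buildEdgeStats(subsetGroup(standardizeCohort(coh, "own-group"), "g"))
  A1 <- adjacency(thresholdToGraph(e, alpha = 0.01))
  A5 <- adjacency(thresholdToGraph(e, alpha = 0.05))
  expect_true(all(A5[A1 == 1] == 1))
  expect_lte(sum(A1), sum(A5))
})

test_that("graphs are symmetric, hollow, and carry provenance", {
  coh <- generateCohort(groupSpec("g", 60, rWithin = 0.4, rBetween = 0.1),
                        canonicalBattery(), seed = 14)
  g <- buildGroupGraph(standardizeCohort(coh, "own-group"), "g")
  A <- adjacency(g)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_identical(g@group, "g")
  expect_identical(g@covariates, c("age", "education"))
})

test_that("excluding education flags few edges when it has no effect", {
  # the education-sensitivity hook: with zero planted education effects,
  # the set of edges changed by dropping the regressor is near-empty
  set.seed(41)
  fracs <- vapply(1:5, function(i) {
    coh <- generateCohort(
      groupSpec("g", 70, rWithin = 0.4, rBetween = 0.1,
                ageEffect = -0.03, educationEffect = 0),
      canonicalBattery(), seed = 500 + i)
    z <- standardizeCohort(coh, "own-group")
    gFull <- buildGroupGraph(z, "g")
    gAge <- buildGroupGraph(z, "g", covariates = "age")
    mean(adjacency(gFull) != adjacency(gAge))
  }, 0.0)
  expect_lt(mean(fracs), 0.05)
})
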