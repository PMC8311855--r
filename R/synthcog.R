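#' Specify one synthetic cohort group
#'
#' A group is a sample of subjects whose latent test scores follow a
#' block correlation structure: pairs of tests sharing a cognitive
#' domain correlate at \code{rWithin} (on the Spearman scale), all other
#' pairs at \code{rBetween}. \code{rBetween} is the group's
#' dedifferentiation level: older and impaired groups are emulated with
#' larger between-domain correlation, mirroring the tendency of
#' cognitive performances to co-vary across domains in aging and
#' disease.
#'
#' @param name unique group label.
#' @param n number of subjects (at least 10).
#' @param rWithin,rBetween target within- and between-domain Spearman
#'   correlations, with \code{0 <= rBetween <= rWithin < 1}.
#' @param ageRange,educationRange,mmseRange uniform sampling bounds
#'   (years / points).
#' @param ageEffect,educationEffect additive linear effect of one year
#'   of age (resp. education), centred at the range midpoint, on every
#'   test's latent score; either a scalar or a per-test named vector.
#' @param missingTests test names absent for this group (columns emitted
#'   as all-missing, as when a test was not in a subgroup's protocol).
#' @param marginalTransform \code{"skew"} applies the monotone transform
#'   \code{exp(x)} to every score so marginals are non-normal while the
#'   Spearman structure is untouched; \code{"none"} leaves Gaussian
#'   scores.
#' @return A \code{groupSpec} list understood by
#'   \code{\link{generateCohort}}.
#' @export
groupSpec <- function(name, n, rWithin = 0.5, rBetween = 0.1,
                      ageRange = c(18, 90), educationRange = c(5, 20),
                      mmseRange = c(24, 30),
                      ageEffect = 0, educationEffect = 0,
                      missingTests = character(0),
                      marginalTransform = c("skew", "none")) {
  stopifnot(is.character(name), length(name) == 1L)
  if (n < 10) stopf("group '%s': n must be >= 10", name)
  if (!(rBetween >= 0 && rBetween <= rWithin && rWithin < 1)) {
    stopf("group '%s': need 0 <= rBetween <= rWithin < 1", name)
  }
  structure(list(
    name = name, n = as.integer(n),
    rWithin = rWithin, rBetween = rBetween,
    ageRange = ageRange, educationRange = educationRange,
    mmseRange = mmseRange,
    ageEffect = ageEffect, educationEffect = educationEffect,
    missingTests = as.character(missingTests),
    marginalTransform = match.arg(marginalTransform)
  ), class = "groupSpec")
}

#' The default six-group study design
#'
#' Three healthy age strata plus amnestic MCI, non-amnestic MCI and
#' dementia groups, sized as in a typical memory-clinic cohort
#' (n = 75/75/70/75/60/60). The dedifferentiation gradient rises from
#' \code{rBetween} = 0.05 in the young group through 0.15 (middle-aged)
#' and 0.30 (older) to 0.30-0.40 in the patient groups, with
#' \code{rWithin} = 0.5 throughout; both Prose Memory measures are
#' missing from the young group's protocol, so its tables carry 14
#' usable tests. Every test receives a mild age decline (-0.03 latent SD
#' per year) and education benefit (+0.05 per year), which the partial
#' correlations downstream are expected to remove.
#'
#' @param battery battery the groups are scored on; defaults to
#'   \code{\link{canonicalBattery}}.
#' @return Named list of \code{\link{groupSpec}}s.
#' @export
defaultStudyGroups <- function(battery = canonicalBattery()) {
  prose <- intersect(c("ProseMemory_Immediate", "ProseMemory_Delayed"),
                     testNames(battery))
  specs <- list(
    groupSpec("young", 75, rWithin = 0.5, rBetween = 0.05,
              ageRange = c(18, 39), educationRange = c(8, 20),
              mmseRange = c(27, 30), ageEffect = -0.03,
              educationEffect = 0.05, missingTests = prose),
    groupSpec("middle", 75, rWithin = 0.5, rBetween = 0.15,
              ageRange = c(40, 64), educationRange = c(8, 20),
              mmseRange = c(28, 30), ageEffect = -0.03,
              educationEffect = 0.05),
    groupSpec("older", 70, rWithin = 0.5, rBetween = 0.30,
              ageRange = c(65, 85), educationRange = c(8, 20),
              mmseRange = c(26, 30), ageEffect = -0.03,
              educationEffect = 0.05),
    groupSpec("aMCI", 75, rWithin = 0.5, rBetween = 0.35,
              ageRange = c(60, 90), educationRange = c(5, 18),
              mmseRange = c(24, 28), ageEffect = -0.03,
              educationEffect = 0.05),
    groupSpec("naMCI", 60, rWithin = 0.5, rBetween = 0.30,
              ageRange = c(60, 90), educationRange = c(5, 18),
              mmseRange = c(24, 29), ageEffect = -0.03,
              educationEffect = 0.05),
    groupSpec("dementia", 60, rWithin = 0.5, rBetween = 0.40,
              ageRange = c(60, 90), educationRange = c(5, 18),
              mmseRange = c(17, 24), ageEffect = -0.03,
              educationEffect = 0.05)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Target Spearman correlation matrix for a battery
#'
#' Builds the block correlation target: unit diagonal, \code{rWithin}
#' where two tests share at least one cognitive domain, \code{rBetween}
#' elsewhere (tests assigned to no domain correlate at \code{rBetween}
#' with everything). The matrix is verified positive semi-definite;
#' overlapping domain memberships can in principle break this, so it is
#' checked rather than assumed.
#'
#' @param battery a \code{\linkS4class{TestBattery}}.
#' @param rWithin,rBetween block correlations, \code{0 <= rBetween <=
#'   rWithin < 1}.
#' @return Symmetric matrix with test dimnames.
#' @export
#' @examples
#' R <- buildTargetCorrelation(syntheticBattery(2, 3), 0.5, 0.1)
#' eigen(R, only.values = TRUE)$values
buildTargetCorrelation <- function(battery, rWithin, rBetween) {
  tests <- testNames(battery)
  if (!length(tests)) stopf("battery is empty")
  if (!(rBetween >= 0 && rBetween <= rWithin && rWithin < 1)) {
    stopf("need 0 <= rBetween <= rWithin < 1")
  }
  p <- length(tests)
  R <- matrix(rBetween, p, p, dimnames = list(tests, tests))
  for (i in seq_len(p)) {
    di <- battery@domains[[i]]
    if (!length(di)) next
    for (j in seq_len(p)) {
      if (i != j && length(intersect(di, battery@domains[[j]]))) {
        R[i, j] <- rWithin
      }
    }
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stopf("target correlation matrix is not positive semi-definite (smallest eigenvalue %.3e)",
          min(ev))
  }
  R
}

## Spearman -> Pearson conversion for Gaussian latents: a bivariate
## normal with Pearson correlation r has population Spearman rho =
## (6/pi) asin(r/2); inverting plants the *Spearman* target exactly.
spearmanToPearson <- function(rho) 2 * sin(pi * rho / 6)

## Symmetric square root via eigendecomposition (tolerates PSD targets
## that Cholesky would reject).
matrixRoot <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-10) {
    stopf("latent correlation matrix is not positive semi-definite (smallest eigenvalue %.3e)",
          min(e$values))
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic multi-group cognitive cohort
#'
#' For each group, ages and educations are drawn uniformly from the
#' group's ranges, latent test scores from a zero-mean Gaussian whose
#' correlation plants the group's Spearman block targets (a Gaussian
#' copula: the Pearson latent correlation is pre-distorted by
#' \code{2 sin(pi rho / 6)} so the \emph{Spearman} block means match),
#' covariate effects are added linearly (centred at the range
#' midpoints), and an optional monotone skew transform makes marginals
#' non-normal without touching ranks. Tests in a group's
#' \code{missingTests} are emitted as all-\code{NA} columns. Output is
#' byte-identical for a fixed seed.
#'
#' @param groups a single \code{\link{groupSpec}} or list of them
#'   (unique names).
#' @param battery the \code{\linkS4class{TestBattery}} scoring the
#'   cohort.
#' @param seed integer seed governing all randomness in the draw.
#' @return A \code{\linkS4class{CognitiveCohort}} with raw scores.
#' @export
#' @examples
#' g <- groupSpec("g1", 20, rWithin = 0.5, rBetween = 0.1,
#'                marginalTransform = "none")
#' generateCohort(g, syntheticBattery(2, 3), seed = 1)
generateCohort <- function(groups, battery, seed = NULL) {
  if (is(groups, "groupSpec")) groups <- list(groups)
  nm <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("group names must be unique")
  tests <- testNames(battery)
  withSeed(seed, {
    parts <- lapply(groups, function(g) .generateGroup(g, battery))
  })
  scores <- do.call(cbind, lapply(parts, `[[`, "scores"))
  subjects <- do.call(rbind, lapply(parts, `[[`, "subjects"))
  CognitiveCohort(scores, subjects, battery)
}

.generateGroup <- function(g, battery) {
  tests <- testNames(battery)
  p <- length(tests)
  bad <- setdiff(g$missingTests, tests)
  if (length(bad)) {
    stopf("group '%s': missingTests not in battery: %s", g$name,
          paste(bad, collapse = ", "))
  }
  Rs <- buildTargetCorrelation(battery, g$rWithin, g$rBetween)
  Rp <- spearmanToPearson(Rs)
  diag(Rp) <- 1
  L <- matrixRoot(Rp)

  age <- runif(g$n, g$ageRange[1], g$ageRange[2])
  edu <- runif(g$n, g$educationRange[1], g$educationRange[2])
  mmse <- round(runif(g$n, g$mmseRange[1], g$mmseRange[2]))
  Z <- matrix(rnorm(g$n * p), g$n, p) %*% L    # subjects x tests latents

  betaAge <- rep_len(g$ageEffect, p)
  betaEdu <- rep_len(g$educationEffect, p)
  if (!is.null(names(g$ageEffect)) && length(g$ageEffect) > 1) {
    betaAge <- g$ageEffect[tests]
  }
  if (!is.null(names(g$educationEffect)) && length(g$educationEffect) > 1) {
    betaEdu <- g$educationEffect[tests]
  }
  ageC <- age - mean(g$ageRange)
  eduC <- edu - mean(g$educationRange)
  S <- Z + outer(ageC, betaAge) + outer(eduC, betaEdu)
  ## Latents live on a performance scale (higher = better). Tests scored
  ## as time/error counts run the other way, so their raw scores are the
  ## negated performance value; the orientation step downstream flips
  ## them back.
  rev <- !isHigherBetter(battery)[tests]
  S[, rev] <- -S[, rev]
  if (g$marginalTransform == "skew") S <- exp(S)
  S[, tests %in% g$missingTests] <- NA_real_

  scores <- t(S)
  dimnames(scores) <- list(tests,
                           sprintf("%s_%03d", g$name, seq_len(g$n)))
  subjects <- data.frame(
    subject = colnames(scores),
    group = g$name,
    age = age,
    education = edu,
    mmse = mmse,
    stringsAsFactors = FALSE
  )
  list(scores = scores, subjects = subjects)
}
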