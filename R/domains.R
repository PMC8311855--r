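#' Domain-wise mean node metrics
#'
#' Averages each node metric over the member tests of every cognitive
#' domain present in the graph. A test belonging to several domains
#' (e.g. Similarities sits in both semantic processing and abstract
#' reasoning) contributes to each; members absent from the graph (e.g.
#' Prose Memory in a 14-test group) are simply left out of the mean. A
#' domain with no present member yields an \code{NA} profile, never
#' zeros.
#'
#' @param metrics node-metric data.frame from \code{\link{nodeMetrics}}.
#' @param battery the \code{\linkS4class{TestBattery}} defining domain
#'   membership.
#' @return data.frame with one row per domain: \code{domain},
#'   \code{n_members} (present members), and the mean of
#'   \code{betweenness}, \code{clustering}, \code{local_efficiency},
#'   \code{global_efficiency}, \code{density}.
#' @export
domainMeans <- function(metrics, battery) {
  cols <- c("betweenness", "clustering", "local_efficiency",
            "global_efficiency", "density")
  rows <- lapply(.COGNITIVE_DOMAINS, function(d) {
    members <- intersect(domainMembers(battery, d), metrics$node)
    vals <- if (length(members)) {
      colMeans(metrics[metrics$node %in% members, cols, drop = FALSE])
    } else {
      setNames(rep(NA_real_, length(cols)), cols)
    }
    cbind(data.frame(domain = d, n_members = length(members),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}

#' Intra- vs inter-domain correlation consistency
#'
#' For the whole cohort (all groups pooled), computes the partial
#' Spearman correlation of every relevant test pair controlling for
#' age, education and MMSE, maps coefficients through the Fisher
#' transform \code{z = atanh(rho)}, and contrasts, per domain, the mean
#' z over within-domain pairs with the mean z over member-by-non-member
#' pairs. A domain whose tests hang together shows intra > inter.
#'
#' @param cohort a z-scored \code{\linkS4class{CognitiveCohort}}
#'   covering the whole cohort, with the covariate columns present in
#'   \code{colData}.
#' @param covariates covariates partialled out (default age, education
#'   and MMSE, the whole-cohort correction set).
#' @param battery battery defining the domains; defaults to the
#'   cohort's.
#' @return data.frame with one row per domain: mean Fisher z and pair
#'   count for intra- and inter-domain pairs, plus the back-transformed
#'   means (\code{tanh} of the mean z). A pair with |rho| = 1 is an
#'   error (infinite z), reported with the pair named.
#' @export
domainConsistency <- function(cohort,
                              covariates = c("age", "education", "mmse"),
                              battery = NULL) {
  if (is.null(battery)) battery <- batteryOf(cohort)
  if (is.null(battery)) stopf("no battery available")
  S <- t(scoreMatrix(cohort))
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  missingCov <- setdiff(covariates, names(cd))
  if (length(missingCov)) {
    stopf("covariate(s) not in colData: %s",
          paste(missingCov, collapse = ", "))
  }
  covM <- as.matrix(cd[, covariates, drop = FALSE])
  tests <- colnames(S)[colSums(!is.na(S)) > 0]

  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pairs <- combn(tests, 2)
  z <- setNames(numeric(ncol(pairs)), pairKey(pairs[1, ], pairs[2, ]))
  for (i in seq_len(ncol(pairs))) {
    est <- partialSpearman(S[, pairs[1, i]], S[, pairs[2, i]], covM)
    if (abs(est$rho) >= 1) {
      stopf("|rho| = 1 for pair %s - %s: Fisher z undefined",
            pairs[1, i], pairs[2, i])
    }
    z[i] <- atanh(est$rho)
  }

  rows <- lapply(.COGNITIVE_DOMAINS, function(d) {
    members <- intersect(domainMembers(battery, d), tests)
    nonMembers <- setdiff(tests, members)
    intraKeys <- if (length(members) >= 2) {
      mp <- combn(members, 2)
      pairKey(mp[1, ], mp[2, ])
    } else character(0)
    interKeys <- as.vector(outer(members, nonMembers, pairKey))
    zi <- z[intraKeys]; ze <- z[interKeys]
    data.frame(
      domain = d,
      intra_mean_z = if (length(zi)) mean(zi) else NA_real_,
      inter_mean_z = if (length(ze)) mean(ze) else NA_real_,
      intra_mean_rho = if (length(zi)) tanh(mean(zi)) else NA_real_,
      inter_mean_rho = if (length(ze)) tanh(mean(ze)) else NA_real_,
      intra_pairs = length(zi),
      inter_pairs = length(ze),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
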