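#' Write / read a binary adjacency matrix CSV
#'
#' The interchange format between stages: a square 0/1 matrix with the
#' test labels as header row and first column.
#'
#' @param graph a \code{\linkS4class{CognitiveGraph}}.
#' @param file path to write/read.
#' @return \code{readAdjacencyCSV} returns a \code{CognitiveGraph}
#'   (provenance fields unset); writers return \code{file} invisibly.
#' @export
writeAdjacencyCSV <- function(graph, file) {
  A <- adjacency(graph)
  write.csv(A, file, row.names = TRUE)
  invisible(file)
}

#' @rdname writeAdjacencyCSV
#' @export
readAdjacencyCSV <- function(file) {
  A <- as.matrix(read.csv(file, row.names = 1, check.names = FALSE))
  colnames(A) <- rownames(A)
  CognitiveGraph(A)
}

#' Export a graph as a two-column edge list
#'
#' @inheritParams writeAdjacencyCSV
#' @export
writeEdgeListCSV <- function(graph, file) {
  A <- adjacency(graph)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(source = rownames(A)[idx[, 1]],
                   target = rownames(A)[idx[, 2]])
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a graph as GraphML with node attributes
#'
#' Writes a GraphML file consumable by external layout tools (Gephi and
#' the like), carrying per-node community id, betweenness and hub flag
#' when a node-metric table is supplied.
#'
#' @inheritParams writeAdjacencyCSV
#' @param metrics optional node-metric data.frame from
#'   \code{\link{nodeMetrics}} (rows matched by node name).
#' @export
writeGraphML <- function(graph, file, metrics = NULL) {
  A <- adjacency(graph)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (!is.null(metrics)) {
    idx <- match(rownames(A), metrics$node)
    igraph::V(g)$community <- metrics$community[idx]
    igraph::V(g)$betweenness <- metrics$betweenness[idx]
    igraph::V(g)$hub <- metrics$hub[idx]
  }
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Pipeline configuration
#'
#' Builds (or reads from a flat YAML key-value file) the configuration
#' driving \code{\link{runPipeline}}. Recognized keys mirror the
#' arguments below; \code{readPipelineConfig} fills unstated keys with
#' these defaults.
#'
#' @param cohortFile optional path to a cohort CSV; when \code{NULL}
#'   a synthetic cohort is generated from
#'   \code{\link{defaultStudyGroups}} under \code{seed}.
#' @param batteryFile optional battery CSV; default
#'   \code{\link{canonicalBattery}}.
#' @param normSource referencing scheme for network formation (see
#'   \code{\link{standardizeCohort}}).
#' @param alpha edge significance level.
#' @param covariates covariates partialled out of every edge.
#' @param nPerm permutations for the in-band validation (0 disables).
#' @param dropNegative negative-edge policy.
#' @param usePermutationInBand decide in-band edges on the permutation
#'   p.
#' @param seed master seed for generation, permutations and Louvain.
#' @param louvainRestarts best-of-R Louvain runs.
#' @param comparisonPairs list of 2-vectors of group names to contrast;
#'   \code{NULL} means every group pair.
#' @return A \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(cohortFile = NULL, batteryFile = NULL,
                           normSource = "own-group", alpha = 0.05,
                           covariates = c("age", "education"),
                           nPerm = 0, dropNegative = TRUE,
                           usePermutationInBand = FALSE, seed = 1,
                           louvainRestarts = 1,
                           comparisonPairs = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(
    cohortFile = cohortFile, batteryFile = batteryFile,
    normSource = normSource, alpha = alpha, covariates = covariates,
    nPerm = nPerm, dropNegative = dropNegative,
    usePermutationInBand = usePermutationInBand, seed = seed,
    louvainRestarts = louvainRestarts, comparisonPairs = comparisonPairs
  ), class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param file path to a YAML config file.
#' @export
readPipelineConfig <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipelineConfig, vals)
}

#' Run the full cognitive-network pipeline
#'
#' End-to-end orchestration: load or generate the cohort, standardize
#' per group, build each group's edge statistics and binary graph,
#' derive node metrics, communities and domain profiles, run the
#' whole-cohort domain-consistency analysis and the configured
#' between-group metric contrasts, and (optionally) write every product
#' plus a run manifest to \code{outDir}. Reruns with an identical
#' config produce identical numeric outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory; \code{NULL} skips file output.
#' @param quiet suppress progress logging.
#' @return (invisibly) a list: \code{cohort}, \code{zscored},
#'   \code{edges}, \code{graphs}, \code{metrics}, \code{domainProfiles}
#'   (per group), \code{consistency}, \code{comparisons},
#'   \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        quiet = FALSE) {
  logf <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  battery <- if (!is.null(config$batteryFile)) {
    readBattery(config$batteryFile)
  } else {
    canonicalBattery()
  }
  cohort <- if (!is.null(config$cohortFile)) {
    logf("stage cohort: reading %s", config$cohortFile)
    readCohort(config$cohortFile, battery)
  } else {
    logf("stage cohort: generating synthetic cohort (seed %d)",
         config$seed)
    generateCohort(defaultStudyGroups(battery), battery,
                   seed = config$seed)
  }
  logf("stage standardize: norm source '%s'", config$normSource)
  z <- standardizeCohort(cohort, config$normSource)

  groups <- groupNames(cohort)
  edges <- list(); graphs <- list(); metrics <- list(); profiles <- list()
  for (g in groups) {
    logf("stage netbuild: group '%s'", g)
    e <- buildEdgeStats(subsetGroup(z, g), covariates = config$covariates,
                        nPerm = config$nPerm, seed = config$seed)
    sk <- attr(e, "skipped")
    if (!is.null(sk)) {
      for (i in seq_len(nrow(sk))) {
        logf("  skipped pair %s-%s: %s", sk$test_a[i], sk$test_b[i],
             sk$reason[i])
      }
    }
    gr <- thresholdToGraph(e, alpha = config$alpha,
                           dropNegative = config$dropNegative,
                           usePermutationInBand =
                             config$usePermutationInBand)
    m <- nodeMetrics(gr, seed = config$seed,
                     restarts = config$louvainRestarts)
    edges[[g]] <- e; graphs[[g]] <- gr; metrics[[g]] <- m
    profiles[[g]] <- domainMeans(m, battery)
  }

  logf("stage domains: whole-cohort consistency")
  consistency <- domainConsistency(z, battery = battery)

  pairs <- config$comparisonPairs
  if (is.null(pairs) && length(groups) > 1) {
    cp <- combn(groups, 2)
    pairs <- lapply(seq_len(ncol(cp)), function(i) cp[, i])
  }
  fam <- length(pairs)
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    compareMetrics(metrics[[p[1]]], metrics[[p[2]]],
                   groupA = p[1], groupB = p[2], familySize = fam)
  }))

  manifest <- c(
    sprintf("cognet_version: %s", as.character(packageVersion("cognet"))),
    sprintf("seed: %d", config$seed),
    sprintf("alpha: %g", config$alpha),
    sprintf("norm_source: %s", config$normSource),
    sprintf("covariates: %s", paste(config$covariates, collapse = ",")),
    sprintf("n_perm: %d", config$nPerm),
    sprintf("drop_negative: %s", config$dropNegative),
    sprintf("use_permutation_in_band: %s", config$usePermutationInBand),
    sprintf("louvain_restarts: %d", config$louvainRestarts),
    sprintf("groups: %s", paste(groups, collapse = ",")),
    sprintf("cohort_file: %s", config$cohortFile %||% "(synthetic)"),
    sprintf("comparison_family_size: %d", fam)
  )

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(cohort, file.path(outDir, "cohort.csv"))
    writeBattery(battery, file.path(outDir, "battery.csv"))
    for (g in groups) {
      write.csv(edges[[g]], file.path(outDir, paste0("edges_", g, ".csv")),
                row.names = FALSE)
      writeAdjacencyCSV(graphs[[g]],
                        file.path(outDir, paste0("adjacency_", g, ".csv")))
      writeEdgeListCSV(graphs[[g]],
                       file.path(outDir, paste0("edgelist_", g, ".csv")))
      writeGraphML(graphs[[g]],
                   file.path(outDir, paste0("graph_", g, ".graphml")),
                   metrics[[g]])
      write.csv(metrics[[g]],
                file.path(outDir, paste0("metrics_", g, ".csv")),
                row.names = FALSE)
      write.csv(metrics[[g]][, c("node", "community")],
                file.path(outDir, paste0("partition_", g, ".csv")),
                row.names = FALSE)
      write.csv(profiles[[g]],
                file.path(outDir, paste0("domains_", g, ".csv")),
                row.names = FALSE)
    }
    write.csv(consistency, file.path(outDir, "consistency.csv"),
              row.names = FALSE)
    write.csv(comparisons, file.path(outDir, "comparisons.csv"),
              row.names = FALSE)
    writeLines(manifest, file.path(outDir, "manifest.txt"))
    logf("bundle written to %s", outDir)
  }

  invisible(list(cohort = cohort, zscored = z, edges = edges,
                 graphs = graphs, metrics = metrics,
                 domainProfiles = profiles, consistency = consistency,
                 comparisons = comparisons, manifest = manifest))
}
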