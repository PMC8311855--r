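Package: cognet
Title: Graph-Theoretical Analysis of Cognitive Test Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds group-level cognitive networks from neuropsychological
    test batteries: raw scores are norm-referenced to z-scores, pairwise
    partial Spearman correlations (controlling age and education, with
    permutation validation of borderline p-values) are thresholded into
    binary undirected graphs, and node-level graph-theory metrics
    (betweenness centrality, clustering coefficient, local and global
    efficiency, connection density, Louvain communities, hub flags) are
    derived per group and per cognitive domain. Includes nonparametric
    group contrasts (Mann-Whitney U, Kruskal-Wallis with Dunn post hoc,
    chi-square) with Bonferroni correction, and a synthetic multi-group
    cohort generator with planted block correlation structure for testing
    cognitive dedifferentiation analyses without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, StatisticalMethod
RoxygenNote: 7.3.3
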