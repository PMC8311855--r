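# cognet

Graph-theoretical analysis of cognitive test covariance networks.

Clinical neuropsychology reads a patient's profile test by test; cognet
reads it as a system. For each group of subjects (healthy age strata,
MCI subtypes, dementia), the package builds a graph whose nodes are the
tests of a neuropsychological battery and whose edges are significant
partial Spearman correlations between test scores, controlling for age
and education:

- edge rule: rank-transform scores and covariates, residualize ranks on
  the covariates, correlate residuals; keep the edge iff the two-tailed
  p from *t* = ρ·√((n−2−k)/(1−ρ²)) on n−2−k df is < 0.05 and ρ > 0
  (negative edges are removed by default, retained as a sensitivity
  analysis); borderline p-values (0.01 < p < 0.1) are re-checked with a
  5000-randomization Freedman–Lane permutation test;
- per node: betweenness centrality BC(v) = Σ σ_st(v)/σ_st, clustering
  coefficient C(v) = 2e_N(v)/(k_v(k_v−1)), local efficiency (global
  efficiency of the neighbour-induced subgraph), global efficiency
  E(v) = mean of 1/d(v,u), connection density k_v/(N−1), Louvain
  community, and a hub flag (BC > mean + 1.5 SD);
- per domain (memory, semantic, abstract reasoning, executive): mean
  node metrics, and a whole-cohort intra- vs inter-domain consistency
  contrast on Fisher-transformed partial correlations (controlling age,
  education and MMSE);
- between groups: two-tailed Mann–Whitney U on node-metric vectors,
  Kruskal–Wallis H + Dunn post hoc on scores, chi-square on categorical
  demographics, all Bonferroni-corrected with the family size logged.

Rising whole-network density, clustering and efficiency along the age
and disease gradient quantify *cognitive dedifferentiation* — the
increasing cross-domain coupling of performances. A seeded synthetic
cohort generator with planted Spearman block structure (Gaussian copula
latents, monotone-skew marginals, linear age/education effects, missing
test protocols) stands in for participant data, so the whole pipeline
is testable end to end.

It is intended for researchers in neuropsychology and aging who want a
reproducible, scriptable implementation of covariance-network analysis,
and for methodologists studying when such networks recover planted
structure.

## A worked example

```r
library(cognet)
battery <- canonicalBattery()                       # the 16-test battery
cohort  <- generateCohort(defaultStudyGroups(battery), battery, seed = 1)
z       <- standardizeCohort(cohort, "own-group")   # self-normed z-scores
graph   <- buildGroupGraph(z, "older", alpha = 0.05)
graph
#> CognitiveGraph: 16 nodes, 83 edges
#>   group: older | alpha: 0.05 | negative edges: drop
#>   covariates: age, education
```

The older synthetic stratum (planted between-domain correlation 0.30)
yields a dense graph: 83 of 120 possible edges, whole-network density
`wholeDensity(graph)` = 0.692. Node metrics and domain profiles:

```r
metrics <- nodeMetrics(graph, seed = 1)
domainMeans(metrics, battery)
#>      domain n_members betweenness clustering global_efficiency density
#> 1    memory         4        3.32      0.691             0.883   0.767
#> 2  semantic         3        1.74      0.759             0.844   0.689
#> 3  abstract         3        2.00      0.749             0.856   0.711
#> 4 executive         4        2.25      0.718             0.850   0.700
```

Contrasting the sparse young graph (planted between-domain correlation
0.05, 14 tests) against the older one shows the dedifferentiation
signal where it should be — density and global efficiency — while
betweenness does not separate:

```r
young <- buildGroupGraph(z, "young")
compareMetrics(nodeMetrics(young, seed = 1), metrics, familySize = 3)
#>             measure   U    p_raw p_adjusted significant
#> 1       betweenness 111 9.83e-01   1.00e+00       FALSE
#> 2        clustering  57 2.32e-02   6.96e-02       FALSE
#> 3  local_efficiency  57 2.32e-02   6.96e-02       FALSE
#> 4 global_efficiency   0 3.36e-06   1.01e-05        TRUE
#> 5           density   0 3.28e-06   9.83e-06        TRUE
```

Here U = 0 means complete separation of the two groups' 14 and 16
node-density values; the adjusted p applies a Bonferroni factor of 3
(one per group pair in a three-group analysis).

`runPipeline(pipelineConfig(seed = 1), outDir = "run1")` executes the
whole study — six groups, edge statistics, adjacency/GraphML/edge-list
exports, node metrics, partitions, domain profiles, consistency table,
comparison table and a run manifest — deterministically from one seed.
A thin command-line wrapper with the same stages lives at
`inst/scripts/cognet.R`. The methods vignette
(`vignettes/cognitive-networks.Rmd`) documents the model, the
generator's assumptions and every numerical choice.

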