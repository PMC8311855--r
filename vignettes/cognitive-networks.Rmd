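---
title: "Modelling cognitive test batteries as covariance networks"
author: "cognet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive test batteries as covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognet)
```

## The model

Human cognition is organized into partially separable domains — memory,
semantic processing, abstract reasoning, executive functioning — whose
performances nonetheless co-vary. cognet treats a group's
neuropsychological profile as an undirected graph: each cognitive test
is a node, and an edge joins two tests whose scores correlate
significantly across the group's subjects once age and education are
partialled out. Changes in the topology of that graph across age strata
and patient groups operationalize *cognitive dedifferentiation*: the
tendency, in aging and in neurodegenerative disease, for performances in
different domains to become more strongly interrelated, yielding denser,
more clustered, more efficient covariance graphs.

The pipeline is:

1. **Standardization.** Raw scores become norm-referenced z-scores,
   `z = (raw - mean)/SD`, with reverse-oriented tests (time and error
   counts, where more is worse) multiplied by −1 so that higher always
   means better. Three referencing schemes are exposed because a
   clinical study needs all three: `own-group` (each group against its
   own moments — the scheme used before building each control group's
   network), `overall` (pooled healthy reference, for between-group
   score comparisons) and `matched` (patients against their matched
   control group).
2. **Network formation.** For every pair of tests, the partial Spearman
   correlation controlling age and education: rank-transform all
   variables (average ranks at ties), regress each rank vector on the
   ranked covariates plus intercept, and correlate the residuals. The
   analytic two-tailed p comes from
   `t = rho * sqrt((n-2-k)/(1-rho^2))` on `n-2-k` degrees of freedom.
   Edges with `p < alpha` (strict, default 0.05) enter a binary
   adjacency matrix; significant *negative* correlations are removed by
   default because binary graph metrics are validated on positively
   connected networks (a `dropNegative = FALSE` sensitivity path keeps
   them as unsigned edges). Borderline p-values (0.01 < p < 0.1) are
   re-checked by a seeded permutation test with 5000 randomizations.
3. **Graph metrics.** Per node: betweenness centrality (Brandes),
   clustering coefficient, local and global efficiency, connection
   density, Louvain community and a hub flag (betweenness more than 1.5
   sample SDs above the graph mean). All are implemented from first
   principles on the binary adjacency matrix and verified in the test
   suite against brute-force path-enumeration and exhaustive-partition
   oracles, and against igraph where definitions coincide.
4. **Domain profiles.** Node metrics averaged over each domain's member
   tests, and a whole-cohort intra- vs inter-domain consistency
   analysis: partial Spearman correlations (adding MMSE to the
   covariates, since the whole cohort spans health and dementia) are
   Fisher-transformed (`z = atanh(rho)`) and averaged within domains
   and across member-by-non-member pairs.
5. **Contrasts.** Two-tailed Mann-Whitney U between the node-metric
   vectors of two graphs, Kruskal-Wallis H with Dunn post hoc tests on
   test scores, chi-square for categorical demographics — all with
   Bonferroni correction and an explicitly logged family size.

## The synthetic cohort generator

No participant-level data ship with the package, so every stage is
exercised on synthetic cohorts with *planted* correlation structure.
Latent scores are Gaussian-copula style: a zero-mean Gaussian vector
whose correlation matrix is block-structured — `rWithin` for test pairs
sharing a domain, `rBetween` otherwise — followed by an optional
monotone skew transform (`exp`), which makes marginals non-normal
without moving a single rank. Because the pipeline thresholds *Spearman*
correlations, the Pearson latent correlation is pre-distorted by
`r = 2*sin(pi*rho/6)` so that the planted *Spearman* values are hit
exactly in expectation. The block target is verified positive
semi-definite (smallest eigenvalue ≥ −1e−10) rather than assumed,
because overlapping domain memberships can break it.

Age and education are drawn uniformly from per-group ranges and enter
each test additively (defaults −0.03 and +0.05 latent SD per year,
centred at the range midpoints): strong enough that failing to partial
them out visibly distorts the network, weak enough not to dominate the
planted blocks. Reverse-oriented tests emit raw scores on a negated
performance scale, so their raw correlations with other tests are
negative until the orientation step flips them — as with real timed
measures.

The default six-group design mirrors a memory-clinic cohort: healthy
young (n = 75, ages 18–39), middle-aged (75, 40–64) and older (70,
65–85) strata plus aMCI (75), naMCI (60) and dementia (60) groups, with
a dedifferentiation gradient `rBetween` = 0.05 / 0.15 / 0.30 rising to
0.30–0.40 in patients and `rWithin` = 0.5 throughout. Both Prose Memory
measures are absent from the young group's protocol, so its tables
carry 14 usable tests (91 candidate edges instead of 120). MMSE is
drawn from group-appropriate ranges so the whole-cohort consistency
analysis can correct for it.

What the generator deliberately does **not** emulate: real score
ranges, ceilings and floors, test-specific reliabilities, non-uniform
age distributions, and any direct dependence of the correlation
structure on the covariates. Passing tests therefore demonstrate that
the machinery recovers known structure under a Gaussian-copula world;
they do not validate clinical claims about any particular cohort.

## Two designed-in properties worth knowing

Two behaviours of the planted design are easy to misread as bugs:

- **Mean clustering is not monotone in `rBetween`.** At `rWithin = 0.5`
  and n = 75 the within-domain edge power is essentially 1, so the
  sparsest (young-like) graphs are unions of near-cliques whose members
  have clustering close to 1. Mean clustering therefore starts *high*,
  dips as stray between-domain edges dilute clique neighbourhoods, and
  only then rises with density. Whole-network density and global
  efficiency, by contrast, increase cleanly along the gradient. In real
  cohorts the young group's *within*-domain correlations are themselves
  weak, which is what makes an empirical clustering trend monotone.
- **Planted blocks are not always the modularity optimum.** With
  `rBetween = 0.1` at n = 75, each between-domain pair has roughly 13%
  edge power, so a sampled graph carries a correlated handful of stray
  edges; frequently a partition other than the planted one has strictly
  higher Newman Q, and Louvain (correctly) returns that one. Exact
  block recovery from sampled cohorts at these settings is therefore a
  coin-flip-to-moderate event, even though the Louvain implementation
  attains the exhaustive-search optimum on most small graphs and never
  exceeds it.

## Numerical and design choices

- **Ties** get average ranks everywhere.
- **Pairwise-listwise deletion**: each edge uses the complete cases of
  its two tests and the covariates, maximizing n per pair; every
  skipped pair is logged with a reason, never dropped silently.
- **Permutation test**: Freedman-Lane on ranks — one residualized rank
  vector is permuted and re-residualized on the covariate ranks, so the
  permutation null lives on the same residual subspace as the analytic
  t. The p-value carries the add-one correction
  `(1 + #{|rho*| >= |rho|}) / (nPerm + 1)`, making the smallest
  attainable p explicit. By default the permutation p is a *check* on
  the analytic p; `usePermutationInBand = TRUE` makes it the in-band
  decision rule instead.
- **Betweenness** counts unordered pairs and is left unnormalized,
  matching the reference-toolbox convention; whether a source counted
  ordered pairs (a factor of 2) is immaterial to hub flags and
  contrasts, which are scale-invariant.
- **Local efficiency** is the global efficiency of the subgraph induced
  by a node's neighbours (the node excluded) — note that igraph's
  `local_efficiency()` implements a different variant, which is why the
  test suite checks this metric against a brute-force oracle instead.
- **Louvain** is seeded and run once by default (reproducibility);
  `restarts` keeps the best-Q partition over independently seeded runs
  when quality matters more. Isolated nodes are singleton communities;
  an edgeless graph has Q defined as 0.
- **Hub rule** uses the sample (n−1) SD, as does norm computation.
- **Bonferroni families** are per-metric (the number of group pairs
  tested on that metric) by default and are always recorded in the
  output, so any alternative convention is auditable.
- **Node metrics are not independent observations**: the Mann-Whitney
  contrast between two graphs' metric vectors is the conventional
  analysis for covariance networks, not a calibrated inferential test.
  A subject-relabelling alternative (rebuild graphs under permuted
  group labels) can be layered on top by the user; it is deliberately
  not the default because it answers a different question.
- **Inter-domain consistency** uses member-by-non-member pairs (not
  non-member-by-non-member), matching the "each domain test against
  every test outside the domain" reading; pair counts `C(m,2)` and
  `m(T-m)` are asserted exactly in the tests.

## A worked example

```{r example, eval = FALSE}
battery <- canonicalBattery()
cohort <- generateCohort(defaultStudyGroups(battery), battery, seed = 1)
z <- standardizeCohort(cohort, "own-group")

edges <- buildEdgeStats(subsetGroup(z, "older"), nPerm = 5000, seed = 1)
graph <- thresholdToGraph(edges, alpha = 0.05)
metrics <- nodeMetrics(graph, seed = 1)
domainMeans(metrics, battery)
domainConsistency(z)

res <- runPipeline(pipelineConfig(seed = 1), outDir = "run1")
```

The problem sizes used throughout the test suite — groups of 60–75
subjects, 16-test batteries, 50–500 replicate cohorts, 2000-replicate
null calibrations, exhaustive graph oracles up to 10 nodes — were
chosen so that Monte-Carlo error is small relative to the tolerances
being asserted while a full run stays comfortably interactive.

## Limitations

- Binary graphs only: the thresholding step discards correlation
  magnitude, and no weighted-metric variants are provided.
- No Gaussian graphical model / regularized-precision estimation: with
  markedly non-normal scores the rank-based route is the appropriate
  one, and proportional thresholding is deliberately avoided because it
  promotes non-significant coefficients to edges.
- Domain profiles are theory-driven; Louvain communities are reported
  alongside but never substituted for the domain definitions.
- The generator's uniform covariates and linear effects are a
  convenience, not a demographic model.
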