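---
title: "Community assembly and interaction networks along salinity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community assembly and interaction networks along salinity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Inland lakes in arid and semi-arid regions are salinizing, and bacterial
communities respond long before macro-organisms do.  Two questions dominate
the analysis of a salinity-gradient survey of such lakes:

1. **Assembly** — is community turnover along the gradient driven by
   deterministic selection (environmental filtering) or by stochastic
   processes (dispersal and drift)?  The standard instrument is the beta
   nearest taxon index (betaNTI), a standardized effect size of
   phylogenetic turnover against a null model, read against fixed ±2
   thresholds.
2. **Interactions** — how does the architecture of co-occurrence networks
   (edge signs, degree, density, modularity, path length) change with
   salinity, and are the observed networks distinguishable from random
   graphs?

`salinet` implements the full arc for both questions — rarefaction, alpha
diversity, core occupancy, Levins niche breadth, Bray–Curtis + PerMANOVA, a
multivariate regression tree, betaMNTD/betaNTI, an ensemble co-occurrence
network with resampling-based edge support, and Erdős–Rényi topology
nulls — together with a synthetic community generator whose ground truth
makes every stage testable.

## Phylogenetic turnover and the betaNTI null model

For samples $A$ and $B$ with cophenetic tip distances $d(i,j)$,

$$\beta\mathrm{MNTD}(A,B) = \tfrac12\Big[\sum_{i \in A} f_{iA}\,
\min_{j \in B} d(i,j) + \sum_{j \in B} f_{jB}\, \min_{i \in A} d(j,i)\Big],$$

where the weights $f$ are $1/\text{richness}$ (presence-based, the package
default) or relative abundances (`weighted = TRUE`).  A taxon present in
both samples contributes a nearest-taxon distance of zero.

The null model shuffles tip labels across the whole tree ("taxa shuffle");
both communities of a pair are evaluated against the same shuffled tree in
each of the `n_null` iterations (999 in a full analysis).  Then

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{\mathrm{obs}} -
\overline{\beta\mathrm{MNTD}}_{\mathrm{null}}}{\mathrm{SD}
(\beta\mathrm{MNTD}_{\mathrm{null}})},$$

with $>2$ read as variable selection, $<-2$ as homogeneous selection, and
the interval $[-2, 2]$ (boundary included — the thresholds are strict
inequalities) as stochastic assembly.  Pairs whose null SD is zero
(identical communities are the canonical case) are reported as undefined
with a warning rather than silently dropped.

**Why presence-based weights by default.**  The literature uses both
variants and survey papers rarely say which they ran; the widely used
picante implementation defaults to the presence-based form, so that is the
likelier provenance of published values, and it is the package default
here.  There is also a small-community argument: under abundance weighting
the statistic is dominated by the few most abundant taxa, which are
typically shared between samples and contribute zero; at desk scale
(hundreds rather than thousands of taxa) the effective number of
contributing taxa drops to a handful and |betaNTI| is strongly attenuated.
The presence-based form spreads the statistic over all non-shared taxa and
retains its resolution.  `weighted = TRUE` restores the abundance-weighted
variant.

A Mantel test (`phylo_signal()`) checks the premise that close relatives
occupy similar salinities: per-taxon optima are estimated as
abundance-weighted mean sample salinity and correlated against cophenetic
distances under permutation.

## PerMANOVA and the regression tree

`permanova()` implements the one-way pseudo-F directly from the distance
matrix:

$$SS_{\mathrm{total}} = \tfrac1n \sum_{i<j} d_{ij}^2, \qquad
SS_{\mathrm{within}} = \sum_g \tfrac{1}{n_g} \sum_{i<j \in g} d_{ij}^2,$$

$$F = \frac{(SS_{\mathrm{total}} - SS_{\mathrm{within}})/(g-1)}
{SS_{\mathrm{within}}/(n-g)},$$

with the add-one permutation estimator $p = (1 + \#\{F_\pi \ge F\})/(1+m)$,
which can never return zero.  On Euclidean distances of univariate data the
pseudo-F equals the classical one-way ANOVA F; the test suite asserts this
equivalence to $10^{-9}$ and checks the permutation p against exhaustive
enumeration at $n = 8$.

`mrt_fit()` is a multivariate regression tree: greedy binary partitioning
of the Hellinger-transformed community matrix (square-rooted relative
abundances; switchable to raw proportions) on environmental thresholds.
Candidate thresholds are midpoints of consecutive sorted unique values of
each predictor; each step takes the split with the largest reduction in
within-node sum of squares (ties broken by predictor order, then smaller
threshold).  Growth is best-first, which yields a nested tree sequence;
tree size is selected by minimum 10-fold cross-validated relative error
(not the 1-SE rule — chosen for determinism and simplicity; both the CV
curve and its fold-wise standard errors are reported), with seeded fold
assignment, and the selected size is refit on the full data.
`cv_folds = 0` skips pruning; `max_depth = 0` forces the root-only tree.

## The ensemble co-occurrence network

Inference follows the ensemble/ReBoot lineage:

1. **Occupancy filter** — only taxa present in ≥ 80% of samples enter
   (`ceiling(0.8 n)` boundary; idempotent).
2. **Five measures** — Pearson and Spearman on per-sample relative
   abundances (similarities); Kendall distance $(1-\tau_b)/2$, Bray–Curtis
   between across-sample profiles, and symmetrized Kullback–Leibler
   divergence on pseudocounted (+1) profiles (dissimilarities).  τ_b is
   computed for all pairs at once via a sign-matrix crossproduct and
   profile Bray–Curtis via the Manhattan-distance identity; both are
   asserted against `cor(..., method = "kendall")` and `vegan::vegdist` in
   the tests.
3. **Candidates** — per measure, the 500 top- and 500 bottom-ranked pairs;
   the candidate set is the union over measures (a pair extreme under only
   one measure still enters).  Ranking ties break lexicographically by
   taxon pair, so the set is deterministic.
4. **Permutation support** — each iteration independently reshuffles every
   taxon's profile and recomputes all pairwise scores in one vectorised
   pass; this realises the independence null for every pair
   simultaneously at a fraction of the per-edge cost.  By default the
   profiles are permuted as fixed vectors (auditable, no re-closure);
   `renorm = TRUE` permutes raw counts and recomputes the per-sample
   closure, the CoNet-like compositional variant.
5. **p-values** — the two-tailed centred empirical estimator
   $(1+b)/(1+n_{\mathrm{perm}})$ is primary.  When the observed deviation
   exceeds every permutation draw this saturates at its resolution limit,
   so the default `p_method = "hybrid"` then extrapolates with a Gaussian
   fitted to the null.  The empirical part protects the tails against the
   skew of the dissimilarity nulls (a pure Gaussian fit is anticonservative
   on the short side); the Gaussian part lets genuinely extreme edges carry
   p-values far below the resolution limit, without which a
   Benjamini–Hochberg step over a thousand candidates could never accept
   anything.
6. **Stability filter** — 95% percentile bootstrap interval of each score
   over resampled samples (degenerate replicates with an all-zero taxon are
   redrawn, capped at 10× the requested count); an edge–measure whose
   permutation-null mean falls inside the interval is discarded as
   unstable.
7. **Simes merge and BH** — surviving per-measure p-values merge as
   $\min_i\, m\, p_{(i)}/i$; BH runs across edges with the *full candidate
   count* as the number of tests, so edges dropped by the stability filter
   count as performed tests rather than silently shrinking the correction.
   At $n = 45$ samples, chance correlations of $|r| \approx 0.45$ occur by
   the dozen among ~1,700 pairs; fixing the test universe is what keeps
   them out of the accepted set.
8. **Signs** — majority vote of surviving measures (score above the null
   mean means co-presence for a similarity and exclusion for a
   dissimilarity); exact ties are discarded and counted in the report.

## Topology and the Erdős–Rényi null

Metrics are computed on the unsigned skeleton (sign fractions are reported
separately): average degree $2E/N$, density $2E/(N(N-1))$, average path
distance as the mean unweighted shortest path within the largest connected
component (empirical co-occurrence networks are routinely disconnected),
and modularity from deterministic greedy (CNM-style) agglomeration.
`er_null()` samples $G(n, m)$ graphs — edge count fixed, matching the
"same numbers of nodes and edges" convention — and standardises each metric
into a z-score with an empirical two-sided p.  Density and average degree
are fixed by construction under $G(n,m)$; their null SD is zero and the
z-score is reported as undefined with a warning.

## The synthetic community generator

The generator emulates a four-lake salinity-gradient survey: 45 samples in
groups of 16/13/8/8 at mean salinities 0.47/0.74/2.48/6.22 per-mille,
sequencing depths uniform in [59,188, 95,000] reads (the floor is the
rarefaction depth of such surveys; the ceiling brackets their mean), and a
Yule phylogeny with salinity optima evolved by Brownian motion so niche
similarity is heritable.

Expected relative abundance of taxon $i$ at salinity $s$ is

$$\lambda_i(s) \propto \exp(b_i)\,
\exp\!\big(-(s-\mu_i)^2 / 2\sigma_i^2\big)\, \varepsilon,$$

a Gaussian niche response times log-normal noise, with counts multinomial
at the drawn depth.  Planted associations act on the log-scale latent noise
through a Gaussian copula (equicorrelated blocks or pairs), so
compositional closure cannot erase them.  `neutral = TRUE` switches the
niche term off entirely, yielding group labels with no compositional
signal — the null configuration for every calibration check.

Default parameters (all overridable): `bm_rate = 3` and `root_optimum = 3`
per-mille put optima across the full 0.5–6 per-mille gradient with strong
phylogenetic signal; `tolerance_mean = 2` per-mille gives moderate
filtering; `baseline_sd = 2.5` and `noise_sd = 1.5` produce the
heavy-tailed rank-abundance curve and sparse occupancy (per-sample richness
a small fraction of the taxon pool) that real rarefied OTU tables show;
`salinity_cv = 0.05` adds within-lake environmental variation.  The default
pool is 300 taxa — a desk-scale stand-in for the thousands of OTUs of a
real survey; pass `n_taxa` explicitly for more.

Scaled-down runs in the tests preserve the survey's
reads-per-present-taxon ratio (roughly 185) by shrinking depth together
with the pool (for example depth 3,000–7,000 at 100–600 taxa), and the
60-taxon network benchmarks use `baseline_sd = noise_sd = 0.8` so the top
taxon holds under ~10% of the reads, the dominance profile of a real
table.  Without that, a single dominant taxon couples every relative
abundance through closure and "independent" taxa are not independent.

What the generator does **not** emulate: sequencing error and chimeras,
taxon-specific detection bias, spatial or temporal autocorrelation,
dispersal limitation (so betaNTI's stochastic regime is pure drift), and
genuinely compositional interaction mechanisms.  Passing tests therefore
demonstrate internal statistical correctness and qualitative
reproducibility of the gradient patterns, not performance on any
particular real data set.

## Numerical and design choices

* Simpson diversity is the Gini–Simpson form $1-\sum p^2$ (a decrease
  toward saline lakes then reads naturally as lost diversity); Shannon uses
  the natural log.
* Levins niche breadth $B_j = 1/\sum_h P_{jh}^2$ takes the individual
  sample as the habitat unit; the community value is the unweighted mean
  over taxa present in the sample.  Both choices are conventions, not
  forced by theory; abundance-weighted community means would emphasise
  dominant taxa.
* Rarefaction is a single seeded draw without replacement; taxa that end up
  empty are retained unless `drop_empty = TRUE` (the pipeline drops them).
* All permutation p-values use the add-one estimator.
* Identifiers are case-sensitive and whitespace-trimmed; Newick trees with
  missing branch lengths are an error unless `missing_lengths = "zero"` is
  requested explicitly, because phylogenetic turnover with silently
  defaulted lengths is meaningless.
* Every stochastic routine takes a `seed`; the pipeline derives per-stage
  seeds from its master seed by hashing the stage name, so any stage can be
  rerun in isolation and a fixed master seed makes the whole run (and its
  JSON report) byte-reproducible.

## Known limitations

* The MRT is a self-contained reimplementation (best-first growth, minimum
  CV error); it does not reproduce every behaviour of the classical
  `mvpart` implementation, in particular surrogate splits and the 1-SE
  rule.
* betaNTI stops at the selection/stochastic partition; partitioning the
  stochastic fraction further (dispersal limitation vs homogenizing
  dispersal vs drift via Raup–Crick) is out of scope.
* The network stage quantifies co-occurrence, not mechanistic interaction;
  with `renorm = FALSE` the permutation null tests independence of the
  observed relative-abundance profiles, and strong compositional effects
  (a few dominant taxa) will surface as real associations.
* $G(n,m)$ nulls fix only the node and edge counts; degree-preserving
  (configuration-model) nulls are not implemented.

## A minimal session

```{r example}
library(salinet)

sim <- simulate_dataset(n_taxa = 300, seed = 1,
                        depth_range = c(5000, 9000))
rare <- rarefy_counts(sim$otu, seed = 1, drop_empty = TRUE)

alpha_diversity(rare)
permanova(bray_curtis(rare), sim$env$group, seed = 1)
bn <- bnti(rare, sim$tree, n_null = 199, seed = 1)
table(bn$pairs$class)

net <- infer_network(rare, n_perm = 200, n_boot = 200, seed = 1)
er_null(topology_metrics(net), n_reps = 1000, seed = 1)
```

The same arc, with every output written to disk and a deterministic JSON
report, is one call:

```{r pipeline}
cfg <- pipeline_config(out_dir = "run", seed = 1,
                       simulate = list(n_taxa = 300,
                                       depth_range = c(5000, 9000)),
                       n_null = 199, net_n_perm = 200, net_n_boot = 200)
report <- run_pipeline(cfg)
```
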