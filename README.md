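# salinet

Community assembly and interaction-network analysis for bacterial
communities along lake salinity gradients.

Salinization of inland lakes reshapes their bacterial communities, and two
statistical instruments dominate the analysis of salinity-gradient surveys:
the **beta nearest taxon index (βNTI)**, a null-model standardized effect
size of phylogenetic turnover that separates deterministic selection from
stochastic assembly, and **ensemble co-occurrence networks**, whose
topology (signs, degree, density, modularity, path length) tracks community
stability across the gradient.  `salinet` implements the full workflow for
OTU-table surveys:

* rarefaction, richness/Shannon/Simpson, Core100/Core80 occupancy,
  Levins niche breadth `B = 1/Σ P²`;
* Bray–Curtis dissimilarity with one-way **PerMANOVA**
  (`pseudo-F = ((SS_T − SS_W)/(g−1)) / (SS_W/(n−g))`, label-permutation p);
* a **multivariate regression tree** on environmental predictors
  (Hellinger response, best-first growth, 10-fold CV pruning);
* **βMNTD/βNTI** with the taxa-shuffle null (999 randomizations by
  default) and the ±2 classification into variable selection, homogeneous
  selection, and stochastic assembly, plus a Mantel phylogenetic-signal
  check;
* an **ensemble co-occurrence network**: ≥80% occupancy filter; Pearson,
  Spearman, Kendall distance, Bray–Curtis, and symmetrized
  Kullback–Leibler scores; top/bottom-500 candidate ranking; 1,000
  permutation + 1,000 bootstrap scores per edge and measure with a
  stability filter; Simes p-value merging; Benjamini–Hochberg FDR; signed
  edges by majority vote;
* network **topology metrics** (avgK, density, APD, modularity)
  standardized against 1,000 Erdős–Rényi G(n, m) random graphs;
* a **synthetic salinity-gradient community generator** (Yule phylogeny,
  Brownian-motion salinity niches, Gaussian niche filtering, copula-planted
  taxon associations, multinomial read depths) whose ground truth makes
  every stage testable without sequencing data.

The methods vignette
(`vignettes/salinity-assembly-and-networks.Rmd`) documents the models,
defaults, and design choices in detail.

## A worked example

```r
library(salinet)

sim  <- simulate_dataset(n_taxa = 300, seed = 1, depth_range = c(5000, 9000))
rare <- rarefy_counts(sim$otu, seed = 1, drop_empty = TRUE)

head(alpha_diversity(rare), 3)
#>   sample_id richness  shannon   simpson
#> 1       S01       87 2.180668 0.7164954
#> 2       S02       81 2.286087 0.8156177
#> 3       S03       94 2.344473 0.7418952

permanova(bray_curtis(rare), sim$env$group, seed = 1)
#> PerMANOVA: pseudo-F(3, 41) = 4.332, R2 = 0.2407, p = 0.001 (999 permutations)

bnti(rare, sim$tree, n_null = 199, seed = 1)
#> betaNTI null model: 990 sample pairs, 199 randomizations (unweighted)
#> homogeneous_selection            stochastic    variable_selection
#>                     9                   820                   161

net <- infer_network(rare, n_perm = 200, n_boot = 200, seed = 1)
net
#> Signed co-occurrence network: 19 nodes, 16 edges
#>   positive 11 (68.8%), negative 5; 0 tie(s) discarded

er_null(topology_metrics(net), n_reps = 1000, seed = 1)
#> Topology: 19 nodes, 16 edges, avgK = 1.684, density = 0.0936
#>   APD = 2.311, modularity Q = 0.562
#>   Erdos-Renyi null (1000 reps):
#>       metric    obs null_mean null_sd      z     p
#> 1 avg_degree 1.6842    1.6842  0.0000     NA 1.000
#> 2    density 0.0936    0.0936  0.0000     NA 1.000
#> 3        apd 2.3111    3.1228  0.5401 -1.503 0.131
#> 4 modularity 0.5625    0.5077  0.0686  0.799 0.423
```

Reading the output: PerMANOVA rejects homogeneity of the four lake groups
(p = 0.001, R² = 0.24 of community variance along the gradient).  Most
sample pairs fall in the stochastic βNTI band |βNTI| ≤ 2, as expected under
the generator's moderate default filtering (`tolerance_mean = 2` ‰); narrow
tolerances push within-lake pairs below −2 (homogeneous selection).  The
inferred network keeps only edges whose merged, FDR-corrected support
survives permutation and bootstrap scrutiny; its density and average degree
are fixed by construction under the G(n, m) null (SD 0, z undefined), while
APD and modularity are compared against the random-graph distribution.

The whole workflow, with every stage output and a byte-deterministic JSON
report, is one call:

```r
cfg <- pipeline_config(out_dir = "run", seed = 1,
                       simulate = list(n_taxa = 300,
                                       depth_range = c(5000, 9000)))
report <- run_pipeline(cfg)
```

A thin command-line wrapper lives at `inst/scripts/salinet.R`
(`simulate` and `run` subcommands).

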