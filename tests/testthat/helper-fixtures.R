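# Shared fixture builders.  Everything is generated in code; no stored data.

# tiny OTU table with known structure
toy_otu <- function() {
  m <- matrix(c(5L, 3L, 0L, 2L,
                1L, 0L, 4L, 2L,
                0L, 6L, 1L, 3L), nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"),
                              c("T1", "T2", "T3", "T4")))
  m
}

# two-group, two-lake design used throughout the stochastic checks
two_group_design <- function(n_per = 10L) {
  data.frame(group = c("fresh", "brine"), salinity = c(0.5, 6),
             n = c(n_per, n_per), stringsAsFactors = FALSE)
}

# compositional two-block fixture for the regression tree: community switches
# wholesale at a gap in the salinity gradient
two_block_fixture <- function(n_per_block = 10L, n_taxa = 30L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_block
  counts <- matrix(rpois(n * n_taxa, 5), n, n_taxa)
  counts[seq_len(n_per_block), seq_len(10L)] <-
    counts[seq_len(n_per_block), seq_len(10L)] + rpois(n_per_block * 10L, 100)
  counts[(n_per_block + 1L):n, (n_taxa - 9L):n_taxa] <-
    counts[(n_per_block + 1L):n, (n_taxa - 9L):n_taxa] +
    rpois(n_per_block * 10L, 100)
  dimnames(counts) <- list(sprintf("S%02d", seq_len(n)),
                           sprintf("T%02d", seq_len(n_taxa)))
  env <- data.frame(
    salinity = c(seq(0.2, 1.0, length.out = n_per_block),
                 seq(1.8, 3.0, length.out = n_per_block)),
    row.names = rownames(counts))
  list(counts = counts, env = env, gap_midpoint = (1.0 + 1.8) / 2)
}

# synthetic data set with planted association pairs on otherwise neutral
# 60-taxon tables (45 samples), the network-benchmark configuration: the
# abundance spread is kept at a study-like dominance profile (top taxon
# share < ~10%) so compositional closure does not itself couple taxa
planted_network_sim <- function(seed, rho, n_pairs = 10L, n_taxa = 60L) {
  design <- data.frame(group = c("fresh", "brine"), salinity = c(0.5, 6),
                       n = c(23L, 22L), stringsAsFactors = FALSE)
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, "tree"))
  niche <- evolve_niches(tree, baseline_sd = 0.8,
                         seed = derive_seed(seed, "niche"))
  pairs <- if (n_pairs > 0L) {
    plant_pairs(niche$taxon, n_pairs, rho, seed = derive_seed(seed, "pp"))
  } else NULL
  truth <- synthetic_truth(niche, pairs = pairs, design = design)
  sim <- simulate_counts(truth, neutral = TRUE, noise_sd = 0.8,
                         seed = derive_seed(seed, "counts"))
  list(otu = sim$otu, truth = truth, pairs = pairs)
}

edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b))
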