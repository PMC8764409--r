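test_that("betaMNTD matches hand values on a star tree and shared-taxa logic", {
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  # A = {t1, t2}, B = {t3, t4}: every cross-tip distance is 2
  m <- matrix(c(5L, 5L, 0L, 0L,
                0L, 0L, 5L, 5L), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("t", 1:4)))
  expect_equal(as.vector(bmntd(m, star)), 2)
  expect_equal(as.vector(bmntd(m, star, weighted = TRUE)), 2)

  # identical communities: shared taxa give nearest distance 0
  ident <- matrix(c(3L, 2L, 1L, 0L,
                    3L, 2L, 1L, 0L), 2, 4, byrow = TRUE,
                  dimnames = list(c("A", "B"), paste0("t", 1:4)))
  expect_equal(as.vector(bmntd(ident, star)), 0)

  # equal abundances: weighted and unweighted agree
  eq <- matrix(c(4L, 4L, 0L, 4L,
                 0L, 4L, 4L, 4L), 2, 4, byrow = TRUE,
               dimnames = list(c("A", "B"), paste0("t", 1:4)))
  expect_equal(bmntd(eq, star, weighted = TRUE), bmntd(eq, star))

  empty <- rbind(ident, C = 0L)
  expect_error(bmntd(empty, star), "empty community")
})

test_that("abundance-weighted betaMNTD agrees with the picante implementation", {
  skip_if_not_installed("picante")
  set.seed(11)
  tr <- simulate_tree(40, seed = 11)
  m <- matrix(rpois(8 * 40, 1.5), 8, 40,
              dimnames = list(paste0("S", 1:8), tr$tip.label))
  m <- m[rowSums(m) > 0, ]
  D <- cophenetic(tr)[colnames(m), colnames(m)]
  ref <- picante::comdistnt(m, D, abundance.weighted = TRUE)
  expect_equal(as.matrix(bmntd(m, tr, weighted = TRUE)),
               as.matrix(ref)[rownames(m), rownames(m)],
               tolerance = 1e-12)
})

test_that("betaNTI is reproducible, order-invariant and flags degenerate nulls", {
  sim <- simulate_dataset(n_taxa = 40, design = two_group_design(4L),
                          seed = 5, depth_range = c(1500L, 3000L))
  b1 <- suppressWarnings(bnti(sim$otu, sim$tree, n_null = 99, seed = 9))
  b2 <- suppressWarnings(bnti(sim$otu, sim$tree, n_null = 99, seed = 9))
  expect_identical(b1$pairs, b2$pairs)
  expect_equal(nrow(b1$pairs), choose(nrow(sim$otu), 2))

  # relabeling sample order leaves each pair's value unchanged
  perm <- sample(nrow(sim$otu))
  b3 <- suppressWarnings(bnti(sim$otu[perm, ], sim$tree, n_null = 99,
                              seed = 9))
  k1 <- edge_keys(b1$pairs$sample_a, b1$pairs$sample_b)
  k3 <- edge_keys(b3$pairs$sample_a, b3$pairs$sample_b)
  expect_equal(b1$pairs$bmntd_obs[order(k1)], b3$pairs$bmntd_obs[order(k3)])

  # two identical communities: null SD = 0 -> NA with a warning
  dup <- sim$otu
  dup[2, ] <- dup[1, ]
  expect_warning(bd <- bnti(dup, sim$tree, n_null = 99, seed = 1),
                 "degenerate null")
  pair12 <- bd$pairs$sample_a == rownames(dup)[1] &
    bd$pairs$sample_b == rownames(dup)[2]
  expect_true(is.na(bd$pairs$bnti[pair12]))

  expect_error(bnti(sim$otu, sim$tree, n_null = 10), "n_null")
})

test_that("process classification uses strict +/-2 thresholds", {
  expect_equal(classify_process(2.5), "variable_selection")
  expect_equal(classify_process(-2.5), "homogeneous_selection")
  expect_equal(classify_process(0), "stochastic")
  # the boundary itself is not selection
  expect_equal(classify_process(c(2, -2)), rep("stochastic", 2))
  expect_error(classify_process(NaN), "NaN")
  expect_error(classify_process(NA_real_), "NA")
  expect_equal(classify_process(c(NA, 3), na_ok = TRUE),
               c(NA, "variable_selection"))
})

test_that("phylogenetic-signal Mantel test behaves at both extremes", {
  tr <- simulate_tree(100, seed = 21)
  des <- two_group_design(8L)

  # conserved niches: significant positive signal
  hits <- vapply(1:5, function(s) {
    sim <- simulate_dataset(n_taxa = 100, design = des, seed = s,
                            depth_range = c(2000L, 4000L))
    ps <- phylo_signal(sim$tree, sim$otu, sim$env, n_perm = 199, seed = s)
    ps$r > 0 && ps$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 4L)

  # constant optima: undefined with a warning
  m <- matrix(4L, 6, 10,
              dimnames = list(paste0("S", 1:6), tr$tip.label[1:10]))
  env <- data.frame(salinity = rep(2, 6), row.names = rownames(m))
  expect_warning(ps <- phylo_signal(tr, m, env, n_perm = 99), "identical")
  expect_true(is.na(ps$r))

  # niches shuffled off the tree: no excess of small p-values
  hits <- vapply(1:10, function(s) {
    sim <- simulate_dataset(n_taxa = 60, design = des, seed = s,
                            neutral = TRUE, depth_range = c(2000L, 4000L))
    ps <- phylo_signal(sim$tree, sim$otu, sim$env, n_perm = 99, seed = s)
    !is.na(ps$p) && ps$p < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.3)
})
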