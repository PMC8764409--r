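test_that("rarefaction draws exactly the requested depth", {
  m <- toy_otu() * 10L
  depth <- min(rowSums(m))
  r <- rarefy_counts(m, seed = 1)
  expect_true(all(rowSums(r) == depth))
  expect_true(all(r <= m))

  # a sample already at the target depth is returned unchanged
  m2 <- rbind(m, S4 = c(depth, 0L, 0L, 0L))
  r2 <- rarefy_counts(m2, depth = depth, seed = 1)
  expect_equal(unname(r2["S4", ]), c(depth, 0L, 0L, 0L))

  expect_error(rarefy_counts(m, depth = 1e6), "S1")
  expect_identical(rarefy_counts(m, seed = 3), rarefy_counts(m, seed = 3))
})

test_that("rarefaction preserves expected relative abundance (hypergeometric mean)", {
  # taxon at 20% of a 1000-read sample, rarefied to 500: mean close to 100
  m <- matrix(c(200L, 800L, 500L, 500L), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B")))
  draws <- vapply(1:1000, function(s) {
    rarefy_counts(m, depth = 500, seed = s)["S1", "A"]
  }, numeric(1))
  expect_lt(abs(mean(draws) - 100) / 100, 0.02)
})

test_that("alpha diversity matches closed forms and vegan", {
  uniform <- matrix(5L, 2, 8,
                    dimnames = list(c("S1", "S2"), paste0("T", 1:8)))
  a <- alpha_diversity(uniform)
  expect_equal(a$shannon, rep(log(8), 2))
  expect_equal(a$simpson, rep(1 - 1 / 8, 2))
  expect_equal(a$richness, rep(8L, 2))

  single <- matrix(c(9L, 0L, 7L, 0L), 2, 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("T1", "T2")))
  a <- alpha_diversity(single)
  expect_equal(a$richness, c(1L, 1L))
  expect_equal(a$shannon, c(0, 0))
  expect_equal(a$simpson, c(0, 0))

  counts <- matrix(c(1L, 1L, 2L, 2L, 1L, 1L), 2, 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  a <- alpha_diversity(counts)
  expect_equal(a$shannon[1], -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)))
  expect_equal(a$simpson[1], 1 - (0.0625 + 0.0625 + 0.25))

  set.seed(42)
  m <- matrix(rpois(60, 8), 5, 12,
              dimnames = list(paste0("S", 1:5), paste0("T", 1:12)))
  a <- alpha_diversity(m)
  expect_equal(a$shannon, unname(vegan::diversity(m, "shannon")))
  expect_equal(a$simpson, unname(vegan::diversity(m, "simpson")))

  zero <- rbind(m, Z = 0L)
  expect_warning(az <- alpha_diversity(zero), "all-zero")
  expect_equal(unname(unlist(az[6, -1])), c(0, 0, 0))
})

test_that("core community uses the ceiling occupancy boundary", {
  # 10 samples; a taxon present in 8 is Core80, in 7 is not
  pres8 <- c(rep(1L, 8), 0L, 0L)
  pres7 <- c(rep(1L, 7), 0L, 0L, 0L)
  m <- cbind(in8 = pres8, in7 = pres7, everywhere = 1L)
  rownames(m) <- paste0("S", 1:10)
  core <- core_fraction(m, 0.8)
  expect_true("in8" %in% core$core)
  expect_false("in7" %in% core$core)
  expect_equal(core$threshold, 8L)

  expect_equal(core_fraction(m, 1.0)$core, "everywhere")
  full <- matrix(1L, 4, 3, dimnames = list(paste0("S", 1:4), paste0("T", 1:3)))
  expect_equal(core_fraction(full, 1.0)$fraction, 1.0)
  expect_error(core_fraction(m, 0), "occupancy")
})

test_that("Bray-Curtis matches hand values and its invariants", {
  m <- matrix(c(2L, 2L, 0L,
                0L, 2L, 2L,
                2L, 2L, 0L,
                5L, 0L, 0L,
                0L, 0L, 7L), 5, 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:5), paste0("T", 1:3)))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["S1", "S2"], 0.5)           # 1 - 2*2/8
  expect_equal(d["S1", "S3"], 0)             # identical samples
  expect_equal(d["S4", "S5"], 1)             # disjoint samples
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  z <- rbind(m, Z1 = 0L, Z2 = 0L)
  expect_error(bray_curtis(z), "all-zero")
  dz <- as.matrix(bray_curtis(z, zero_policy = "one"))
  expect_equal(dz["Z1", "Z2"], 1)
})

test_that("Levins niche breadth matches closed forms and bounds", {
  m <- matrix(c(3L, 8L, 1L,
                3L, 0L, 0L,
                3L, 0L, 1L,
                3L, 0L, 2L), 4, 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), c("even", "once", "mix")))
  nb <- niche_breadth(m)
  expect_equal(unname(nb$per_taxon["even"]), 4)    # spread equally over 4
  expect_equal(unname(nb$per_taxon["once"]), 1)    # single-sample taxon
  # proportions (0.25, 0, 0.25, 0.5) -> 1/0.375
  expect_equal(unname(nb$per_taxon["mix"]), 1 / (0.25^2 + 0.25^2 + 0.5^2))

  expect_true(all(nb$per_taxon >= 1 & nb$per_taxon <= nrow(m)))
  # community mean lies within the member range
  for (s in rownames(m)) {
    mem <- nb$per_taxon[m[s, ] > 0]
    expect_gte(nb$per_sample[[s]], min(mem))
    expect_lte(nb$per_sample[[s]], max(mem))
  }

  # permutation-invariance to sample order
  perm <- c(3, 1, 4, 2)
  nb2 <- niche_breadth(m[perm, ])
  expect_equal(nb2$per_taxon, nb$per_taxon)

  mz <- cbind(m, gone = 0L)
  expect_warning(nbz <- niche_breadth(mz), "zero total")
  expect_false("gone" %in% names(nbz$per_taxon))
})
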