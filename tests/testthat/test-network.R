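test_that("occupancy filter uses the ceiling boundary and is idempotent", {
  pres8 <- c(rep(3L, 8), 0L, 0L)
  pres7 <- c(rep(3L, 7), 0L, 0L, 0L)
  m <- cbind(in8 = pres8, in7 = pres7, everywhere = 2L)
  rownames(m) <- paste0("S", 1:10)
  f <- occupancy_filter(m, 0.8)
  expect_setequal(colnames(f), c("in8", "everywhere"))
  expect_identical(occupancy_filter(f, 0.8), f)

  strict <- occupancy_filter(cbind(m, also = 1L), 1.0)
  expect_setequal(colnames(strict), c("everywhere", "also"))
  expect_error(occupancy_filter(m[9:10, c("in8", "in7")], 1.0), "no taxa")
})

test_that("the five association measures match their oracles and self/antitone cases", {
  # constant-sum table so relative abundances keep the constructed ranks:
  # a duplicated profile (self-association) and a perfectly reversed one
  n <- 20
  x <- 10L + seq_len(n)
  set.seed(4)
  t2 <- sample(x)
  # T1 + dup + rev + pad = 120 for every sample; pad2 closes each row to 200
  m <- cbind(T1 = x, dup = x, rev = 60L - x, pad = 60L - x,
             T2 = t2, pad2 = 80L - t2)
  stopifnot(all(m > 0), length(unique(rowSums(m))) == 1L)
  rownames(m) <- paste0("S", 1:n)
  sc <- association_scores(m)$scores

  expect_equal(sc$pearson["T1", "dup"], 1)
  expect_equal(sc$kendall["T1", "dup"], 0)
  expect_equal(sc$bray["T1", "dup"], 0)
  expect_equal(sc$kl["T1", "dup"], 0, tolerance = 1e-12)
  expect_equal(sc$spearman["T1", "rev"], -1)
  expect_equal(sc$kendall["T1", "rev"], 1)

  # oracles: R's kendall cor and vegan's Bray-Curtis on profiles
  rel <- m / rowSums(m)
  expect_equal(sc$kendall, (1 - cor(rel, method = "kendall")) / 2,
               tolerance = 1e-12)
  expect_equal(sc$spearman, cor(rel, method = "spearman"), tolerance = 1e-12)
  bc <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  diag(sc$bray) <- 0
  expect_equal(sc$bray, bc, tolerance = 1e-12)
})

test_that("taxon-profile Bray-Curtis reproduces the hand example", {
  # closed 3-sample table so profile and count scales agree:
  # x = (2,2,0), y = (0,2,2) -> 1 - 2*2/8 = 0.5
  m <- matrix(c(2L, 0L, 2L,
                2L, 2L, 0L,
                0L, 2L, 2L), 3, 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), c("x", "y", "z")))
  sc <- association_scores(m)$scores
  expect_equal(sc$bray["x", "y"], 0.5)
})

test_that("zero-variance taxa are excluded per measure, not globally", {
  set.seed(5)
  # constant-sum samples, so the flat taxon has a truly constant profile
  t1 <- rpois(10, 20)
  t2 <- rpois(10, 20)
  m <- cbind(T1 = t1, T2 = t2, T3 = 100L - t1 - t2, flat = 10L)
  stopifnot(all(m >= 0))
  rownames(m) <- paste0("S", 1:10)
  sc <- association_scores(m)$scores
  expect_true(all(is.na(sc$pearson["flat", c("T1", "T2", "T3")])))
  expect_false(anyNA(sc$pearson[c("T1", "T2", "T3"), c("T1", "T2", "T3")]))
  expect_false(anyNA(sc$kl))
})

test_that("candidate ranking is a deterministic per-measure union", {
  taxa <- paste0("T", 1:4)
  fake <- function(vals) {
    s <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
    s[upper.tri(s)] <- vals
    s[lower.tri(s)] <- t(s)[lower.tri(s)]
    s
  }
  # measure A ranks pair (T1,T2) top; measure B ranks (T3,T4) bottom
  assoc <- list(scores = list(pearson = fake(c(0.9, 0.1, 0.2, 0.3, 0.4, 0.5)),
                              kl = fake(c(5, 4, 3, 2, 1, 0.5))),
                type = c(pearson = "similarity", kl = "dissimilarity"))
  cand <- candidate_edges(assoc, n_top = 1L, n_bottom = 1L)
  k <- edge_keys(cand$taxon_a, cand$taxon_b)
  expect_true(edge_keys("T1", "T2") %in% k)   # pearson top
  expect_true(edge_keys("T3", "T4") %in% k)   # kl bottom (0.5 smallest)
  # union semantics: a pair ranked only by kl still enters
  expect_true(any(!is.na(cand$kl) & is.na(cand$pearson)))

  # ties broken lexicographically: equal scores give a reproducible set
  tie <- list(scores = list(pearson = fake(rep(0.5, 6))),
              type = c(pearson = "similarity"))
  c1 <- candidate_edges(tie, n_top = 2L, n_bottom = 2L)
  c2 <- candidate_edges(tie, n_top = 2L, n_bottom = 2L)
  expect_identical(c1, c2)
  expect_equal(edge_keys(c1$taxon_a, c1$taxon_b)[1], edge_keys("T1", "T2"))

  # small instance: fewer pairs than n_top + n_bottom -> all pairs + warning
  set.seed(6)
  m <- matrix(rpois(100, 10), 10, 10,
              dimnames = list(paste0("S", 1:10), paste0("X", 1:10)))
  expect_warning(all45 <- candidate_edges(association_scores(m), 500, 500),
                 "candidates")
  expect_equal(nrow(all45), 45L)
})

test_that("Simes merging matches hand examples and its bounds", {
  expect_equal(simes_merge(c(0.01, 0.02, 0.03)), 0.03)
  expect_equal(simes_merge(0.2), 0.2)
  expect_equal(simes_merge(c(0.5, 1.0)), 1.0)
  expect_error(simes_merge(c(0, 0.5)), "p-values")
  expect_true(is.na(simes_merge(numeric(0))))

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    s <- simes_merge(p)
    expect_lte(s, min(1, length(p) * min(p)))   # never above Bonferroni
    expect_gte(s, min(p))                        # never below the minimum p
  }
})

test_that("BH q-values follow the step-up rule", {
  single <- bh_fdr(0.04, alpha = 0.05)
  expect_equal(single$q, 0.04)
  expect_true(single$accepted)

  res <- bh_fdr(c(0.01, 0.02, 0.04, 0.8))
  expect_equal(res$q, c(0.04, 0.04, 4 * 0.04 / 3, 0.8))
  expect_true(all(diff(sort(res$q)) >= 0))

  # widening the test universe is conservative
  wide <- bh_fdr(c(0.01, 0.02), n = 10)
  expect_equal(wide$q, c(0.1, 0.1))
  expect_error(bh_fdr(c(0, 0.5)), "p-values")
})

test_that("edge support is seeded-deterministic and calibrated on noise", {
  sim <- planted_network_sim(1, rho = 0.9, n_pairs = 0L, n_taxa = 25L)
  assoc <- association_scores(sim$otu)
  cand <- suppressWarnings(candidate_edges(assoc))
  s1 <- reboot_support(sim$otu, cand, n_perm = 100, n_boot = 100, seed = 2)
  s2 <- reboot_support(sim$otu, cand, n_perm = 100, n_boot = 100, seed = 2)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$ci_lo, s2$ci_lo)

  # independent profiles: per-measure p-values are roughly uniform
  frac05 <- colMeans(s1$p < 0.05, na.rm = TRUE)
  expect_true(all(frac05 < 0.15))
  expect_true(all(s1$p > 0 & s1$p <= 1, na.rm = TRUE))
})

test_that("a planted strong pair earns a tiny Pearson p-value", {
  hits <- vapply(1:5, function(s) {
    sim <- planted_network_sim(s, rho = 0.9, n_pairs = 3L)
    assoc <- association_scores(sim$otu)
    cand <- suppressWarnings(candidate_edges(assoc))
    sup <- reboot_support(sim$otu, cand, n_perm = 200, n_boot = 100,
                          seed = s)
    k <- edge_keys(sup$edges$taxon_a, sup$edges$taxon_b)
    planted <- k %in% edge_keys(sim$pairs$taxon_a, sim$pairs$taxon_b)
    all(sup$p[planted, "pearson"] <= 0.001)
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("sign assignment is a majority vote with ties discarded", {
  mk_support <- function(directions, stable) {
    ne <- nrow(directions)
    ms <- salinet:::MEASURES
    obs <- matrix(0.5, ne, 5, dimnames = list(NULL, ms))
    p <- matrix(1e-6, ne, 5, dimnames = list(NULL, ms))
    structure(list(
      edges = data.frame(taxon_a = paste0("A", seq_len(ne)),
                         taxon_b = paste0("B", seq_len(ne)),
                         stringsAsFactors = FALSE),
      obs = obs, null_mean = obs * 0, null_sd = obs * 0 + 1, p = p,
      ci_lo = obs, ci_hi = obs, stable = stable, direction = directions,
      n_perm = 100L, n_boot = 100L, p_method = "hybrid"
    ), class = "edge_support")
  }
  ms <- salinet:::MEASURES
  dirs <- rbind(rep("co_presence", 5),
                c("co_presence", "mutual_exclusion", rep(NA, 3)),
                rep("mutual_exclusion", 5))
  colnames(dirs) <- ms
  stable <- !is.na(dirs)
  net <- finalize_network(mk_support(dirs, stable), alpha = 0.05)
  expect_equal(nrow(net$edges), 2L)          # the 1-vs-1 tie is discarded
  expect_equal(net$discarded_tie, 1L)
  expect_setequal(net$edges$sign, c("+", "-"))

  # 8 positive + 2 negative edges -> positive fraction 0.8
  dirs10 <- matrix(rep(c(rep("co_presence", 8), rep("mutual_exclusion", 2)),
                       5), 10, 5, dimnames = list(NULL, ms))
  net10 <- finalize_network(mk_support(dirs10, !is.na(dirs10)), alpha = 0.05)
  expect_equal(net10$positive_fraction, 0.8)
})

test_that("end-to-end inference recovers planted structure with signs", {
  sim <- planted_network_sim(3, rho = 0.9)
  net <- infer_network(sim$otu, n_perm = 200, n_boot = 200, seed = 3)
  tk <- edge_keys(sim$pairs$taxon_a, sim$pairs$taxon_b)
  ek <- edge_keys(net$edges$taxon_a, net$edges$taxon_b)
  expect_gte(mean(tk %in% ek), 0.7)
  expect_true(all(net$edges$q <= 0.05))
  expect_true(all(net$edges$sign[ek %in% tk] == "+"))
  expect_true(all(net$nodes %in% colnames(sim$otu)))
})
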