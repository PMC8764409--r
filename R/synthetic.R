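# Synthetic salinity-gradient community generator.  Produces OTU tables,
# ultrametric phylogenies, environmental metadata and a ground-truth record
# (niche parameters, planted taxon associations, group design) so that every
# downstream stage -- diversity, betaNTI, PerMANOVA/MRT, network inference --
# can be exercised against known structure.

#' Default sampling design: four lakes along a salinity gradient
#'
#' 45 samples in four groups (16/13/8/8) at mean salinities
#' 0.47/0.74/2.48/6.22 per-mille, spanning freshwater to brine.
#'
#' @return data.frame with columns `group`, `salinity`, `n`.
#' @export
lake_design <- function() {
  data.frame(
    group = c("R1", "Bosten", "R2", "R3"),
    salinity = c(0.47, 0.74, 2.48, 6.22),
    n = c(16L, 13L, 8L, 8L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a pure-birth (Yule) ultrametric phylogeny
#'
#' @param n_taxa number of tips (>= 2); tips are labelled
#'   `OTU_0001`, `OTU_0002`, ...
#' @param seed RNG seed; the same seed yields an identical tree.
#' @param birth speciation rate of the Yule process.
#' @return a rooted ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, birth = 1) {
  if (!is.numeric(n_taxa) || n_taxa < 2L) stop("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(as.integer(n_taxa), birth = birth,
                                      death = 0))
  tree$tip.label <- sprintf("OTU_%04d", seq_len(as.integer(n_taxa)))
  tree
}

#' Evolve salinity niches along a phylogeny by Brownian motion
#'
#' Salinity optima evolve by Brownian motion from the root value, so closely
#' related taxa inherit similar optima (a positive control for phylogenetic
#' signal and for selection detectable by the betaNTI null model).
#' Tolerances are log-normal around `tolerance_mean`; baseline log-abundances
#' are normal.
#'
#' @param tree `phylo` with branch lengths.
#' @param bm_rate Brownian-motion rate (variance per unit branch length,
#'   non-negative); 0 collapses all optima onto `root_optimum`.
#' @param root_optimum root state of the salinity optimum (per-mille).
#' @param tolerance_mean mean niche tolerance sigma_i (per-mille).
#' @param tolerance_sdlog log-scale SD of the tolerance distribution.
#' @param baseline_sd SD of the baseline log-abundance b_i.
#' @param seed RNG seed.
#' @return data.frame (`taxon`, `optimum`, `tolerance`, `baseline`), one row
#'   per tip in tip order.
#' @export
evolve_niches <- function(tree, bm_rate = 3, root_optimum = 3,
                          tolerance_mean = 2, tolerance_sdlog = 0.5,
                          baseline_sd = 2.5, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.numeric(bm_rate) || length(bm_rate) != 1L || bm_rate < 0) {
    stop("bm_rate must be a single number >= 0")
  }
  n <- length(tree$tip.label)
  with_seed(seed, {
    optima <- if (bm_rate == 0) {
      stats::setNames(rep(root_optimum, n), tree$tip.label)
    } else {
      ape::rTraitCont(tree, model = "BM", sigma = sqrt(bm_rate),
                      root.value = root_optimum)
    }
    tolerance <- stats::rlnorm(n,
                               meanlog = log(tolerance_mean) -
                                 tolerance_sdlog^2 / 2,
                               sdlog = tolerance_sdlog)
    baseline <- stats::rnorm(n, 0, baseline_sd)
    data.frame(taxon = tree$tip.label,
               optimum = as.numeric(optima[tree$tip.label]),
               tolerance = tolerance,
               baseline = baseline,
               stringsAsFactors = FALSE)
  })
}

#' Plant pairwise latent associations
#'
#' Convenience constructor for the planted-pair table consumed by
#' [synthetic_truth()]: `n_pairs` disjoint taxon pairs with latent log-scale
#' correlation `rho` (mutualism for positive, exclusion for negative), or
#' equicorrelated blocks via `block_size`.
#'
#' @param taxa character vector of taxon ids to draw members from.
#' @param n_pairs number of pairs (or blocks).
#' @param rho latent correlation in `[-1, 1]`.
#' @param block_size members per planted block (2 = a simple pair); all
#'   within-block pairs are recorded as ground truth.
#' @param seed RNG seed for member selection.
#' @return data.frame (`taxon_a`, `taxon_b`, `rho`, `block`).
#' @export
plant_pairs <- function(taxa, n_pairs, rho, block_size = 2L, seed = NULL) {
  stopifnot(abs(rho) <= 1, block_size >= 2L)
  need <- n_pairs * block_size
  if (need > length(taxa)) stop("not enough taxa for the requested blocks")
  if (block_size > 2L && rho < -1 / (block_size - 1)) {
    stop("equicorrelation of ", rho, " is not positive semi-definite for ",
         "blocks of ", block_size)
  }
  members <- with_seed(seed, sample(taxa, need))
  blocks <- split(members, rep(seq_len(n_pairs), each = block_size))
  out <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    mem <- sort(blocks[[b]])
    idx <- utils::combn(length(mem), 2L)
    data.frame(taxon_a = mem[idx[1L, ]], taxon_b = mem[idx[2L, ]],
               rho = rho, block = b, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a synthetic ground-truth record
#'
#' @param niche data.frame from [evolve_niches()].
#' @param pairs planted associations ([plant_pairs()] output), or `NULL`.
#' @param design group design ([lake_design()] format).
#' @param bm_rate Brownian-motion rate used for the niches.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(niche, pairs = NULL, design = lake_design(),
                            bm_rate = NA_real_) {
  stopifnot(all(c("taxon", "optimum", "tolerance", "baseline") %in%
                  colnames(niche)))
  if (any(niche$tolerance <= 0)) stop("tolerances must be > 0")
  if (!all(is.finite(niche$optimum))) stop("optima must be finite")
  if (!is.null(pairs) && nrow(pairs)) {
    if (any(abs(pairs$rho) > 1)) stop("|rho| must be <= 1")
    unknown <- setdiff(c(pairs$taxon_a, pairs$taxon_b), niche$taxon)
    if (length(unknown)) {
      stop("planted pairs reference unknown taxa: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (nrow(design) == 0L || sum(design$n) == 0L) stop("empty design")
  structure(list(niche = niche, pairs = pairs, design = design,
                 bm_rate = bm_rate),
            class = "synthetic_truth")
}

# Block-diagonal latent correlation from the planted-pair table.
# Returns a list of blocks, each with member indices and a Cholesky factor.
planted_blocks <- function(pairs, taxa) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  if (is.null(pairs$block)) {
    pairs$block <- seq_len(nrow(pairs))
  }
  lapply(split(pairs, pairs$block), function(pb) {
    mem <- sort(unique(c(pb$taxon_a, pb$taxon_b)))
    k <- length(mem)
    S <- diag(k)
    dimnames(S) <- list(mem, mem)
    for (r in seq_len(nrow(pb))) {
      S[pb$taxon_a[r], pb$taxon_b[r]] <- pb$rho[r]
      S[pb$taxon_b[r], pb$taxon_a[r]] <- pb$rho[r]
    }
    ch <- tryCatch(chol(S), error = function(e) {
      stop("planted correlation block is not positive definite")
    })
    list(idx = match(mem, taxa), chol = ch)
  })
}

#' Simulate OTU counts and matched environmental metadata
#'
#' Expected relative abundance of taxon i in a sample at salinity s is
#' proportional to `exp(b_i) * exp(-(s - mu_i)^2 / (2 sigma_i^2))` times
#' log-normal noise; planted pairs receive correlated log-scale noise through
#' a Gaussian copula, so compositional closure does not destroy them.  Counts
#' are multinomial at a per-sample depth drawn uniformly in `depth_range`.
#' Per-sample salinity jitters log-normally around the group mean so
#' within-group environmental variance exists.
#'
#' @param truth `synthetic_truth` object.
#' @param depth_range integer range of sequencing depths (default spans the
#'   rarefaction floor of 59,188 reads up to 95,000).
#' @param noise_sd SD of the log-scale abundance noise.
#' @param salinity_cv log-scale coefficient of variation of per-sample
#'   salinity around its group mean.
#' @param neutral if `TRUE`, the niche term is switched off (equivalent to
#'   infinite tolerances): group labels carry no compositional signal.
#' @param seed RNG seed.
#' @return list with `otu` (samples x taxa integer matrix), `env`
#'   (data.frame: `salinity`, `group`), and the `truth` used.
#' @export
simulate_counts <- function(truth, depth_range = c(59188L, 95000L),
                            noise_sd = 1.5, salinity_cv = 0.05,
                            neutral = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth_range[1L] < 1e3 || depth_range[2L] > 1e6 ||
      depth_range[1L] > depth_range[2L]) {
    stop("depth_range must be an increasing range within [1e3, 1e6]")
  }
  design <- truth$design
  if (nrow(design) == 0L || sum(design$n) == 0L) stop("empty design")
  niche <- truth$niche
  n_taxa <- nrow(niche)
  n_samples <- sum(design$n)
  blocks <- planted_blocks(truth$pairs, niche$taxon)

  with_seed(seed, {
    group <- rep(design$group, design$n)
    sal_mean <- rep(design$salinity, design$n)
    salinity <- sal_mean * stats::rlnorm(n_samples, -salinity_cv^2 / 2,
                                         salinity_cv)
    depths <- sample(seq(depth_range[1L], depth_range[2L]), n_samples,
                     replace = TRUE)
    counts <- matrix(0L, n_samples, n_taxa,
                     dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                     niche$taxon))
    for (h in seq_len(n_samples)) {
      eps <- stats::rnorm(n_taxa, 0, noise_sd)
      for (bl in blocks) {
        z <- stats::rnorm(length(bl$idx))
        eps[bl$idx] <- as.numeric(crossprod(bl$chol, z)) * noise_sd
      }
      loglam <- niche$baseline + eps
      if (!neutral) {
        loglam <- loglam -
          (salinity[h] - niche$optimum)^2 / (2 * niche$tolerance^2)
      }
      p <- exp(loglam - max(loglam))
      counts[h, ] <- stats::rmultinom(1L, depths[h], p)[, 1L]
    }
    env <- data.frame(salinity = salinity, group = group,
                      row.names = rownames(counts),
                      stringsAsFactors = FALSE)
    list(otu = counts, env = env, truth = truth)
  })
}

#' One-call synthetic data set
#'
#' Builds tree, niches, planted pairs and counts from a master seed with the
#' default four-lake design.
#'
#' @param n_taxa number of taxa (default 300, a desk-scale stand-in for the
#'   ~2,645 OTUs of a full survey; pass the full size explicitly if wanted).
#' @param design group design.
#' @param seed master seed; stage seeds are derived from it.
#' @param neutral switch off niche filtering.
#' @param pairs planted-pair table or `NULL`.
#' @param ... further arguments to [simulate_counts()] and
#'   [evolve_niches()] (`bm_rate`, `tolerance_mean`, `depth_range`,
#'   `noise_sd`, ...).
#' @return list with `otu`, `env`, `tree`, `truth`.
#' @export
simulate_dataset <- function(n_taxa = 300L, design = lake_design(),
                             seed = 1L, neutral = FALSE, pairs = NULL,
                             bm_rate = 3, root_optimum = 3,
                             tolerance_mean = 2, tolerance_sdlog = 0.5,
                             baseline_sd = 2.5, depth_range = c(59188L, 95000L),
                             noise_sd = 1.5, salinity_cv = 0.05) {
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, "tree"))
  niche <- evolve_niches(tree, bm_rate = bm_rate, root_optimum = root_optimum,
                         tolerance_mean = tolerance_mean,
                         tolerance_sdlog = tolerance_sdlog,
                         baseline_sd = baseline_sd,
                         seed = derive_seed(seed, "niche"))
  truth <- synthetic_truth(niche, pairs = pairs, design = design,
                           bm_rate = bm_rate)
  sim <- simulate_counts(truth, depth_range = depth_range,
                         noise_sd = noise_sd, salinity_cv = salinity_cv,
                         neutral = neutral,
                         seed = derive_seed(seed, "counts"))
  list(otu = sim$otu, env = sim$env, tree = tree, truth = truth)
}
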