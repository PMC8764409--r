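# Ensemble co-occurrence network inference: occupancy filter, five
# association measures (Pearson, Spearman, Kendall distance, Bray-Curtis,
# symmetrized Kullback-Leibler), top/bottom candidate ranking, permutation +
# bootstrap edge support with a stability filter, Simes p-value merging,
# Benjamini-Hochberg FDR, and majority-vote edge signs.

MEASURES <- c("pearson", "spearman", "kendall", "bray", "kl")
MEASURE_TYPE <- c(pearson = "similarity", spearman = "similarity",
                  kendall = "dissimilarity", bray = "dissimilarity",
                  kl = "dissimilarity")

#' Occupancy filter for network inclusion
#'
#' Keeps taxa present (count > 0) in at least
#' `ceiling(min_occupancy * n_samples)` samples; the standard noise guard
#' before co-occurrence inference.  Idempotent.
#'
#' @param counts samples x taxa matrix.
#' @param min_occupancy required occupancy in (0, 1] (default 0.8).
#' @return filtered count matrix.
#' @export
occupancy_filter <- function(counts, min_occupancy = 0.8) {
  counts <- validate_otu(counts)
  if (!is.numeric(min_occupancy) || min_occupancy <= 0 || min_occupancy > 1) {
    stop("min_occupancy must be in (0, 1]")
  }
  threshold <- ceiling(min_occupancy * nrow(counts))
  keep <- colSums(counts > 0) >= threshold
  if (!any(keep)) stop("no taxa survive the occupancy filter")
  counts[, keep, drop = FALSE]
}

# Profile matrices the five measures work on: per-sample relative abundances
# (correlations, Kendall, Bray-Curtis) and per-taxon pseudocounted profiles
# normalised across samples (KL).
profile_matrices <- function(counts, pseudocount = 1) {
  rel <- counts / rowSums(counts)
  Q <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  list(rel = rel, Q = Q)
}

# Pairwise Kendall tau-b over columns via the sign-matrix crossproduct:
# tau_b(i, j) = C_ij / sqrt(C_ii C_jj) with C = crossprod(sign diffs).
kendall_tau <- function(x) {
  n <- nrow(x)
  ij <- which(lower.tri(diag(n)), arr.ind = TRUE)
  Sg <- sign(x[ij[, 1L], , drop = FALSE] - x[ij[, 2L], , drop = FALSE])
  C <- crossprod(Sg)
  d <- sqrt(diag(C))
  out <- C / outer(d, d)
  dimnames(out) <- list(colnames(x), colnames(x))
  out
}

# Bray-Curtis between taxon profiles (columns) via the Manhattan identity
# BC(x, y) = sum|x - y| / (sum x + sum y).
bray_profiles <- function(x) {
  M <- as.matrix(stats::dist(t(x), method = "manhattan"))
  s <- colSums(x)
  out <- M / outer(s, s, "+")
  dimnames(out) <- list(colnames(x), colnames(x))
  out
}

# Symmetrized KL divergence between normalised taxon profiles (columns of Q):
# D(p||q) + D(q||p) = sum_h (p_h - q_h)(log p_h - log q_h).
kl_profiles <- function(Q) {
  CE <- crossprod(Q, log(Q))
  out <- diag(CE)[row(CE)] + diag(CE)[col(CE)] - CE - t(CE)
  out <- pmax(out, 0)   # clip tiny negative rounding
  dimnames(out) <- list(colnames(Q), colnames(Q))
  out
}

# All five taxon-pair score matrices from profile matrices.
score_matrices <- function(rel, Q) {
  list(
    pearson = suppressWarnings(stats::cor(rel)),
    spearman = suppressWarnings(stats::cor(apply(rel, 2L, rank))),
    kendall = (1 - kendall_tau(rel)) / 2,
    bray = bray_profiles(rel),
    kl = kl_profiles(Q)
  )
}

#' Five-measure association scores over taxon pairs
#'
#' Computes Pearson r and Spearman rho on per-sample relative abundances
#' (similarity measures), and Kendall distance `(1 - tau_b)/2`, Bray-Curtis
#' between across-sample abundance profiles, and symmetrized
#' Kullback-Leibler divergence on pseudocounted profiles (dissimilarity
#' measures).  A zero-variance taxon gets `NA` under the rank/correlation
#' measures.
#'
#' @param counts samples x taxa matrix (apply [occupancy_filter()] first for
#'   the standard workflow).
#' @param pseudocount added to counts before the KL closure so the
#'   divergence is finite on sparse data.
#' @return list with `scores` (named list of 5 symmetric matrices) and
#'   `type` (similarity/dissimilarity per measure).
#' @export
association_scores <- function(counts, pseudocount = 1) {
  counts <- validate_otu(counts)
  pm <- profile_matrices(counts, pseudocount)
  list(scores = score_matrices(pm$rel, pm$Q), type = MEASURE_TYPE)
}

#' Candidate edges from per-measure top/bottom ranking
#'
#' Per measure, all taxon pairs are ranked by score and the `n_top` highest
#' plus `n_bottom` lowest become candidates; the candidate set is the union
#' over measures.  Ties are broken by lexicographic pair id, so the set is
#' deterministic.  If a measure has no more than `n_top + n_bottom` scored
#' pairs, all its pairs are candidates (with a warning).
#'
#' @param assoc output of [association_scores()].
#' @param n_top,n_bottom edges kept from each end of each measure's ranking.
#' @return data.frame (`taxon_a`, `taxon_b`) plus one tag column per measure
#'   (`"top"`, `"bottom"` or `NA`).
#' @export
candidate_edges <- function(assoc, n_top = 500L, n_bottom = 500L) {
  scores <- assoc$scores
  taxa <- colnames(scores[[1L]])
  m <- length(taxa)
  if (m < 2L) stop("need at least 2 taxa")
  ut <- which(upper.tri(diag(m)), arr.ind = TRUE)
  a <- taxa[ut[, 1L]]
  b <- taxa[ut[, 2L]]
  key <- pair_key(a, b)
  tags <- matrix(NA_character_, nrow(ut), length(scores),
                 dimnames = list(NULL, names(scores)))
  saturated <- FALSE
  for (ms in names(scores)) {
    s <- scores[[ms]][ut]
    ok <- which(!is.na(s))
    if (length(ok) <= n_top + n_bottom) {
      tags[ok, ms] <- "top"
      saturated <- TRUE
      next
    }
    top <- ok[order(-s[ok], key[ok])][seq_len(n_top)]
    bottom <- ok[order(s[ok], key[ok])][seq_len(n_bottom)]
    tags[top, ms] <- "top"
    tags[bottom, ms] <- "bottom"
  }
  if (saturated) {
    warning("fewer scored pairs than n_top + n_bottom for at least one ",
            "measure; all its pairs kept as candidates")
  }
  keep <- rowSums(!is.na(tags)) > 0L
  out <- data.frame(taxon_a = a[keep], taxon_b = b[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tags[keep, , drop = FALSE],
                                  stringsAsFactors = FALSE))
  ord <- order(pair_key(out$taxon_a, out$taxon_b))
  out[ord, , drop = FALSE]
}

#' Permutation and bootstrap support for candidate edges
#'
#' For every candidate edge and measure: a permutation null is built by
#' independently reshuffling each taxon's across-sample profile `n_perm`
#' times and recomputing all pairwise scores.  The two-tailed p-value is the
#' centred empirical tail count
#' `(1 + #{|null - mean| >= |obs - mean|}) / (1 + n_perm)`; when the
#' observed deviation lies beyond every null draw this saturates at
#' `1/(1 + n_perm)`, so the default `p_method = "hybrid"` then extrapolates
#' with a Gaussian fit to the null (as the CoNet/ReBoot lineage does).
#' `"empirical"` and `"gaussian"` force one estimator throughout.  `n_boot` bootstrap resamples of the samples
#' give a percentile confidence interval per score; an edge-measure whose
#' permutation-null mean lies inside that interval is flagged unstable and
#' excluded from merging.  Bootstrap replicates in which a taxon becomes
#' all-zero are redrawn (capped at `10 * n_boot` attempts).
#'
#' @param counts samples x taxa matrix (occupancy-filtered).
#' @param candidates data.frame from [candidate_edges()].
#' @param n_perm,n_boot resampling effort (both >= 100; the reference
#'   analysis setting is 1,000 each).
#' @param seed RNG seed; the result is reproducible under it.
#' @param p_method `"gaussian"` or `"empirical"` (see above).
#' @param renorm recompute the per-sample closure after permuting counts
#'   (the CoNet-like variant) instead of permuting fixed profiles.
#' @param conf bootstrap confidence level.
#' @param pseudocount KL pseudocount.
#' @return object of class `edge_support`: `edges` (taxon_a, taxon_b) and
#'   per-measure matrices `obs`, `null_mean`, `null_sd`, `p`, `ci_lo`,
#'   `ci_hi`, `stable` (logical), `direction` (`"co_presence"` /
#'   `"mutual_exclusion"`).
#' @export
reboot_support <- function(counts, candidates, n_perm = 1000L,
                           n_boot = 1000L, seed = NULL,
                           p_method = c("hybrid", "gaussian", "empirical"),
                           renorm = FALSE, conf = 0.95, pseudocount = 1) {
  p_method <- match.arg(p_method)
  counts <- validate_otu(counts)
  if (n_perm < 100L || n_boot < 100L) stop("n_perm and n_boot must be >= 100")
  taxa <- colnames(counts)
  n <- nrow(counts)
  m <- ncol(counts)
  ia <- match(candidates$taxon_a, taxa)
  ib <- match(candidates$taxon_b, taxa)
  if (anyNA(ia) || anyNA(ib)) stop("candidates reference unknown taxa")
  cidx <- cbind(ia, ib)
  ne <- nrow(cidx)

  pm <- profile_matrices(counts, pseudocount)
  obs_mats <- score_matrices(pm$rel, pm$Q)
  obs <- vapply(obs_mats, function(s) s[cidx], numeric(ne))

  with_seed(seed, {
    perm_scores <- lapply(MEASURES, function(i) matrix(NA_real_, n_perm, ne))
    names(perm_scores) <- MEASURES
    for (r in seq_len(n_perm)) {
      if (renorm) {
        cp <- vapply(seq_len(m),
                     function(j) counts[sample.int(n), j], numeric(n))
        dimnames(cp) <- dimnames(counts)
        pmp <- profile_matrices(cp, pseudocount)
        sm <- score_matrices(pmp$rel, pmp$Q)
      } else {
        relp <- vapply(seq_len(m),
                       function(j) pm$rel[sample.int(n), j], numeric(n))
        Qp <- vapply(seq_len(m),
                     function(j) pm$Q[sample.int(n), j], numeric(n))
        colnames(relp) <- colnames(Qp) <- taxa
        sm <- score_matrices(relp, Qp)
      }
      for (ms in MEASURES) perm_scores[[ms]][r, ] <- sm[[ms]][cidx]
    }

    boot_scores <- lapply(MEASURES, function(i) matrix(NA_real_, n_boot, ne))
    names(boot_scores) <- MEASURES
    attempts <- 0L
    r <- 1L
    while (r <= n_boot) {
      attempts <- attempts + 1L
      if (attempts > 10L * n_boot) {
        stop("bootstrap: too many degenerate resamples")
      }
      rows <- sample.int(n, replace = TRUE)
      cb <- counts[rows, , drop = FALSE]
      if (any(colSums(cb) == 0)) next
      pmb <- profile_matrices(cb, pseudocount)
      sm <- score_matrices(pmb$rel, pmb$Q)
      for (ms in MEASURES) boot_scores[[ms]][r, ] <- sm[[ms]][cidx]
      r <- r + 1L
    }
  })

  null_mean <- vapply(MEASURES,
                      function(ms) colMeans(perm_scores[[ms]]), numeric(ne))
  null_sd <- vapply(MEASURES, function(ms) {
    apply(perm_scores[[ms]], 2L, stats::sd)
  }, numeric(ne))

  pmat <- matrix(NA_real_, ne, length(MEASURES),
                 dimnames = list(NULL, MEASURES))
  for (k in seq_along(MEASURES)) {
    ms <- MEASURES[k]
    z <- (obs[, ms] - null_mean[, ms]) / null_sd[, ms]
    p_gauss <- pmin(1, pmax(2 * stats::pnorm(-abs(z)), 1e-300))
    p_gauss[null_sd[, ms] == 0] <- NA_real_
    dev_obs <- abs(obs[, ms] - null_mean[, ms])
    dev_null <- abs(sweep(perm_scores[[ms]], 2L, null_mean[, ms]))
    hits <- colSums(dev_null >= rep(dev_obs, each = n_perm))
    p_emp <- (1 + hits) / (1 + n_perm)
    pmat[, k] <- switch(p_method,
      empirical = p_emp,
      gaussian = p_gauss,
      hybrid = ifelse(hits > 0L, p_emp, pmin(p_emp, p_gauss))
    )
    pmat[is.na(obs[, ms]), k] <- NA_real_
  }

  alpha2 <- (1 - conf) / 2
  safe_q <- function(x, pr) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    stats::quantile(x, probs = pr, names = FALSE)
  }
  ci_lo <- vapply(MEASURES, function(ms) {
    apply(boot_scores[[ms]], 2L, safe_q, pr = alpha2)
  }, numeric(ne))
  ci_hi <- vapply(MEASURES, function(ms) {
    apply(boot_scores[[ms]], 2L, safe_q, pr = 1 - alpha2)
  }, numeric(ne))

  stable <- !is.na(pmat) & !is.na(ci_lo) & !is.na(ci_hi) &
    (null_mean < ci_lo | null_mean > ci_hi)
  direction <- matrix(NA_character_, ne, length(MEASURES),
                      dimnames = list(NULL, MEASURES))
  for (k in seq_along(MEASURES)) {
    ms <- MEASURES[k]
    higher <- obs[, ms] > null_mean[, ms]
    copres <- if (MEASURE_TYPE[ms] == "similarity") higher else !higher
    direction[, k] <- ifelse(copres, "co_presence", "mutual_exclusion")
    direction[is.na(obs[, ms]), k] <- NA_character_
  }

  structure(list(
    edges = candidates[, c("taxon_a", "taxon_b")],
    obs = obs, null_mean = null_mean, null_sd = null_sd, p = pmat,
    ci_lo = ci_lo, ci_hi = ci_hi, stable = stable, direction = direction,
    n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
    p_method = p_method
  ), class = "edge_support")
}

#' Simes combination of per-measure p-values
#'
#' `merged = min_i (m * p_(i) / i)` over the sorted p-values, capped at 1;
#' valid under the positive dependence typical of association measures
#' computed on the same profiles.
#'
#' @param p numeric vector of p-values in (0, 1]; `NA`s are dropped.
#' @return merged p-value, or `NA` if no p-values remain.
#' @export
simes_merge <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  ps <- sort(p)
  m <- length(ps)
  min(1, min(m * ps / seq_len(m)))
}

#' Benjamini-Hochberg q-values and acceptance
#'
#' Step-up q-values `q_(i) = min_{j >= i} (m * p_(j) / j)`; edges with
#' `q <= alpha` are accepted.
#'
#' @param p numeric p-values in (0, 1].
#' @param alpha FDR level.
#' @param n number of tests the correction spans (defaults to `length(p)`;
#'   the network pipeline passes the full candidate count so edges dropped
#'   by the stability filter still count as performed tests).
#' @return list with `q` and logical `accepted`.
#' @export
bh_fdr <- function(p, alpha = 0.05, n = length(p)) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p-values must be in (0, 1]")
  q <- pmin(1, stats::p.adjust(p, method = "BH", n = max(n, length(p))))
  list(q = q, accepted = !is.na(q) & q <= alpha)
}

new_signed_network <- function(edges, nodes, discarded_tie = 0L,
                               n_candidates = NA_integer_) {
  pos <- sum(edges$sign == "+")
  neg <- sum(edges$sign == "-")
  structure(list(
    nodes = nodes, edges = edges,
    n_positive = pos, n_negative = neg,
    positive_fraction = if (nrow(edges)) pos / nrow(edges) else NA_real_,
    discarded_tie = as.integer(discarded_tie),
    n_candidates = as.integer(n_candidates)
  ), class = "signed_network")
}

#' Finalize a signed network from supported edges
#'
#' Keeps edge-measures that survived the stability filter, Simes-merges
#' their p-values per edge, applies BH FDR across edges, and assigns each
#' accepted edge a sign by majority vote of the surviving measures'
#' directions (co-presence -> `+`, mutual exclusion -> `-`); ties are
#' discarded and counted.
#'
#' @param support `edge_support` from [reboot_support()].
#' @param alpha FDR level for edge acceptance.
#' @return object of class `signed_network` with `nodes` (taxa incident to
#'   accepted edges), `edges` (taxon_a, taxon_b, sign,
#'   n_supporting_measures, merged_p, q), sign fractions and discard counts.
#' @export
finalize_network <- function(support, alpha = 0.05) {
  stopifnot(inherits(support, "edge_support"))
  p_use <- support$p
  p_use[!support$stable] <- NA_real_
  merged <- apply(p_use, 1L, simes_merge)
  has_measure <- !is.na(merged)
  fdr <- bh_fdr(merged[has_measure], alpha = alpha, n = length(merged))
  accepted <- rep(FALSE, length(merged))
  accepted[has_measure] <- fdr$accepted
  qv <- rep(NA_real_, length(merged))
  qv[has_measure] <- fdr$q

  keep <- which(accepted)
  sign <- character(length(keep))
  nsupp <- integer(length(keep))
  tie <- logical(length(keep))
  for (i in seq_along(keep)) {
    e <- keep[i]
    dirs <- support$direction[e, support$stable[e, ] & !is.na(p_use[e, ])]
    nsupp[i] <- length(dirs)
    npos <- sum(dirs == "co_presence")
    nneg <- sum(dirs == "mutual_exclusion")
    if (npos > nneg) sign[i] <- "+"
    else if (nneg > npos) sign[i] <- "-"
    else tie[i] <- TRUE
  }
  edges <- data.frame(
    taxon_a = support$edges$taxon_a[keep],
    taxon_b = support$edges$taxon_b[keep],
    sign = sign,
    n_supporting_measures = nsupp,
    merged_p = merged[keep],
    q = qv[keep],
    stringsAsFactors = FALSE
  )[!tie, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  new_signed_network(edges, nodes, discarded_tie = sum(tie),
                     n_candidates = nrow(support$edges))
}

#' @export
print.signed_network <- function(x, ...) {
  cat("Signed co-occurrence network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(sprintf("  positive %d (%.1f%%), negative %d; %d tie(s) discarded\n",
                x$n_positive, 100 * x$positive_fraction, x$n_negative,
                x$discarded_tie))
  }
  invisible(x)
}

#' End-to-end ensemble network inference
#'
#' Occupancy filter, five-measure scoring, top/bottom candidate ranking,
#' permutation + bootstrap support, Simes merging, BH FDR and sign
#' assignment in one call.
#'
#' @inheritParams reboot_support
#' @inheritParams occupancy_filter
#' @inheritParams candidate_edges
#' @param alpha FDR level.
#' @return `signed_network` (with the `edge_support` attached as
#'   `attr(net, "support")`).
#' @export
infer_network <- function(counts, min_occupancy = 0.8, n_top = 500L,
                          n_bottom = 500L, n_perm = 1000L, n_boot = 1000L,
                          alpha = 0.05, seed = NULL,
                          p_method = c("gaussian", "empirical"),
                          renorm = FALSE, pseudocount = 1) {
  p_method <- match.arg(p_method)
  filtered <- occupancy_filter(counts, min_occupancy)
  assoc <- association_scores(filtered, pseudocount)
  cand <- suppressWarnings(candidate_edges(assoc, n_top, n_bottom))
  support <- reboot_support(filtered, cand, n_perm = n_perm,
                            n_boot = n_boot, seed = seed,
                            p_method = p_method, renorm = renorm,
                            pseudocount = pseudocount)
  net <- finalize_network(support, alpha = alpha)
  attr(net, "support") <- support
  net
}
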