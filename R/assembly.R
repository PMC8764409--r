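# Phylogenetic community assembly: between-community mean nearest taxon
# distance (betaMNTD), its tip-shuffling null model and the standardized
# beta nearest taxon index (betaNTI), the +/-2 process classification, and a
# Mantel test for phylogenetic signal in salinity optima.

# All-pairs betaMNTD from a relative-abundance matrix and a cophenetic
# distance matrix whose columns are aligned with the table's taxa.  The
# max.col trick gives vectorised row minima of each pair's distance block.
bmntd_kernel <- function(rel, D) {
  ns <- nrow(rel)
  pres <- lapply(seq_len(ns), function(i) which(rel[i, ] > 0))
  out <- matrix(0, ns, ns, dimnames = list(rownames(rel), rownames(rel)))
  for (a in seq_len(ns - 1L)) {
    ia <- pres[[a]]
    fa <- rel[a, ia]
    for (b in (a + 1L):ns) {
      ib <- pres[[b]]
      Dsub <- D[ia, ib, drop = FALSE]
      minA <- Dsub[cbind(seq_along(ia),
                         max.col(-Dsub, ties.method = "first"))]
      tD <- t(Dsub)
      minB <- tD[cbind(seq_along(ib),
                       max.col(-tD, ties.method = "first"))]
      out[a, b] <- out[b, a] <-
        0.5 * (sum(fa * minA) + sum(rel[b, ib] * minB))
    }
  }
  out
}

# Relative abundances (weighted) or 1/richness weights (unweighted).
community_weights <- function(counts, weighted) {
  m <- if (weighted) counts else (counts > 0) * 1
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("empty community (all-zero sample): ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  }
  m / tot
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For samples A and B, the mean over taxa of the cophenetic distance to the
#' nearest taxon in the other community, averaged over the two directions and
#' weighted by relative abundance (weighted mode) or equally over present
#' taxa (unweighted, the default -- the convention of the picante
#' implementation this analysis lineage commonly relies on).  A taxon
#' present in both communities contributes a nearest-taxon distance of 0.
#'
#' @param counts samples x taxa matrix.
#' @param tree `phylo` whose tips cover all taxa with nonzero counts.
#' @param weighted use abundance-weighted betaMNTD instead of the
#'   presence-based default.
#' @return `dist` object of betaMNTD values over samples.
#' @export
bmntd <- function(counts, tree, weighted = FALSE) {
  counts <- validate_otu(counts)
  check_ids(counts, tree = tree)
  D <- stats::cophenetic(tree)[colnames(counts), colnames(counts)]
  rel <- community_weights(counts, weighted)
  stats::as.dist(bmntd_kernel(rel, D))
}

#' Beta nearest taxon index (betaNTI) from a tip-shuffling null model
#'
#' Shuffles tip labels across the whole tree `n_null` times (the "taxa
#' shuffle"; both communities of a pair are evaluated against the same
#' shuffled tree in each iteration), recomputes betaMNTD for every sample
#' pair, and standardises the observed value:
#' `betaNTI = (obs - null mean) / null SD`.  `|betaNTI| > 2` marks pairs
#' shaped by selection; see [classify_process()].
#'
#' @param counts samples x taxa matrix.
#' @param tree `phylo` covering the taxa.
#' @param n_null number of randomizations (>= 99; 999 is the standard
#'   analysis setting).
#' @param weighted use abundance-weighted betaMNTD instead of the
#'   presence-based default (see [bmntd()]).
#' @param seed RNG seed; the same seed reproduces the result exactly.
#' @return object of class `bnti_result`: data.frame `pairs` with columns
#'   `sample_a`, `sample_b`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`,
#'   `class`, plus `n_null` and the observed betaMNTD `dist`.  Pairs with
#'   null SD 0 (e.g. identical communities) get `bnti = NA` with a warning.
#' @export
bnti <- function(counts, tree, n_null = 999L, weighted = FALSE, seed = NULL) {
  counts <- validate_otu(counts)
  if (n_null < 99L) stop("n_null must be >= 99")
  check_ids(counts, tree = tree)
  taxa <- colnames(counts)
  D <- stats::cophenetic(tree)[taxa, taxa]
  rel <- community_weights(counts, weighted)
  obs <- bmntd_kernel(rel, D)
  ns <- nrow(rel)
  n_taxa <- length(taxa)

  sums <- matrix(0, ns, ns)
  sqsums <- matrix(0, ns, ns)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_taxa)
      nullv <- bmntd_kernel(rel, D[perm, perm])
      sums <- sums + nullv
      sqsums <- sqsums + nullv^2
    }
  })
  null_mean <- sums / n_null
  null_sd <- sqrt(pmax(sqsums / n_null - null_mean^2, 0) *
                    n_null / (n_null - 1))

  idx <- which(upper.tri(obs), arr.ind = TRUE)
  sdv <- null_sd[idx]
  bnti_v <- ifelse(sdv > 0, (obs[idx] - null_mean[idx]) / sdv, NA_real_)
  if (anyNA(bnti_v)) {
    warning(sum(is.na(bnti_v)),
            " sample pair(s) have a degenerate null (SD = 0); betaNTI ",
            "undefined for them")
  }
  pairs <- data.frame(
    sample_a = rownames(counts)[idx[, 1L]],
    sample_b = rownames(counts)[idx[, 2L]],
    bmntd_obs = obs[idx],
    null_mean = null_mean[idx],
    null_sd = sdv,
    bnti = bnti_v,
    class = classify_process(bnti_v, na_ok = TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, n_null = as.integer(n_null),
                 bmntd_obs = stats::as.dist(obs), weighted = weighted),
            class = "bnti_result")
}

#' @export
print.bnti_result <- function(x, ...) {
  cat("betaNTI null model:", nrow(x$pairs), "sample pairs,",
      x$n_null, "randomizations",
      if (x$weighted) "(abundance-weighted)" else "(unweighted)", "\n")
  print(table(x$pairs$class, useNA = "ifany"))
  invisible(x)
}

#' Classify the assembly process from a betaNTI value
#'
#' `> 2` variable selection, `< -2` homogeneous selection, otherwise (the
#' boundary included) stochastic -- absence of selection, i.e. dispersal
#' and/or drift.
#'
#' @param x numeric vector of betaNTI values.
#' @param na_ok tolerate `NA` inputs (propagated); `NaN` is always an error.
#' @return character vector in `{variable_selection, homogeneous_selection,
#'   stochastic}`.
#' @export
classify_process <- function(x, na_ok = FALSE) {
  if (any(is.nan(x))) stop("betaNTI is NaN")
  if (!na_ok && anyNA(x)) stop("betaNTI is NA")
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x > 2] <- "variable_selection"
  out[!is.na(x) & x < -2] <- "homogeneous_selection"
  out[!is.na(x) & abs(x) <= 2] <- "stochastic"
  out
}

#' Mantel test for phylogenetic signal in salinity niches
#'
#' Estimates each taxon's salinity optimum as the abundance-weighted mean
#' salinity of the samples it occurs in, then Mantel-correlates cophenetic
#' distances with pairwise optimum differences under a permutation test.  A
#' positive, significant r means close relatives occupy similar salinities,
#' the condition for reading betaMNTD turnover as an assembly signal.
#'
#' @param tree `phylo` covering the taxa.
#' @param counts samples x taxa matrix.
#' @param env environmental data.frame with a `salinity` column covering the
#'   samples.
#' @param n_perm Mantel permutations.
#' @param seed RNG seed.
#' @return list with the Mantel statistic `r`, its permutation `p`, and the
#'   per-taxon `optima`.  Constant optima give an `NA` statistic with a
#'   warning.
#' @export
phylo_signal <- function(tree, counts, env, n_perm = 999L, seed = NULL) {
  counts <- validate_otu(counts)
  if (ncol(counts) < 3L) stop("need at least 3 taxa")
  check_ids(counts, tree = tree, env = env)
  sal <- env[rownames(counts), "salinity"]
  totals <- colSums(counts)
  keep <- totals > 0
  opt <- rep(NA_real_, ncol(counts))
  names(opt) <- colnames(counts)
  opt[keep] <- colSums(counts[, keep, drop = FALSE] * sal) / totals[keep]
  use <- names(opt)[keep]
  if (length(use) < 3L) stop("need at least 3 taxa with nonzero counts")
  if (stats::sd(opt[use]) == 0) {
    warning("all estimated optima identical; Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, optima = opt))
  }
  D <- stats::cophenetic(tree)[use, use]
  dopt <- stats::dist(opt[use])
  mt <- with_seed(seed,
                  vegan::mantel(stats::as.dist(D), dopt,
                                permutations = n_perm))
  list(r = unname(mt$statistic), p = mt$signif, optima = opt)
}
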