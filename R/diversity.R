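# Rarefaction, alpha diversity, core-community occupancy, Bray-Curtis
# dissimilarity, and Levins niche breadth.

#' Rarefy an OTU table to a fixed depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads (one
#' seeded draw).  All-zero taxon columns are retained by default so taxon
#' sets stay aligned with the phylogeny.
#'
#' @param counts samples x taxa integer matrix.
#' @param depth target depth; defaults to the minimum sample total (the
#'   convention for community surveys).
#' @param seed RNG seed.
#' @param drop_empty drop taxa that end up with zero counts everywhere.
#' @return rarefied count matrix.
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = NULL,
                          drop_empty = FALSE) {
  counts <- validate_otu(counts)
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  short <- totals < depth
  if (any(short)) {
    stop("depth ", depth, " exceeds the total of sample(s): ",
         paste(rownames(counts)[short], collapse = ", "))
  }
  # vegan warns on small fixture totals; validity is checked above
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(counts, depth)))
  storage.mode(out) <- "integer"
  if (drop_empty) out <- out[, colSums(out) > 0, drop = FALSE]
  out
}

#' Per-sample alpha diversity
#'
#' Richness (taxa with count > 0), Shannon H (natural log) and Gini-Simpson
#' (1 - sum p^2).  An all-zero sample reports 0 for all three with a warning.
#'
#' @param counts samples x taxa matrix (a rarefied table is the usual input).
#' @return data.frame (`sample_id`, `richness`, `shannon`, `simpson`).
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_otu(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    warning("all-zero sample(s) report 0 diversity: ",
            paste(rownames(counts)[totals == 0], collapse = ", "))
  }
  res <- t(apply(counts, 1L, function(x) {
    tot <- sum(x)
    if (tot == 0) return(c(0, 0, 0))
    p <- x[x > 0] / tot
    c(length(p), -sum(p * log(p)), 1 - sum(p^2))
  }))
  data.frame(sample_id = rownames(counts),
             richness = as.integer(res[, 1L]),
             shannon = res[, 2L],
             simpson = res[, 3L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Core community at an occupancy threshold
#'
#' A taxon is core iff it is present (count > 0) in at least
#' `ceiling(occupancy * n_samples)` samples.  The reported fraction is
#' relative to taxa present in at least one sample.
#'
#' @param counts samples x taxa matrix.
#' @param occupancy required occupancy in (0, 1]; 1.0 and 0.8 give the
#'   Core100 and Core80 conventions.
#' @return list with `core` (taxon ids), `fraction`, `threshold` (sample
#'   count required).
#' @export
core_fraction <- function(counts, occupancy) {
  counts <- validate_otu(counts)
  if (!is.numeric(occupancy) || occupancy <= 0 || occupancy > 1) {
    stop("occupancy must be in (0, 1]")
  }
  present <- colSums(counts > 0)
  threshold <- ceiling(occupancy * nrow(counts))
  core <- colnames(counts)[present >= threshold]
  observed <- sum(present > 0)
  list(core = core,
       fraction = if (observed) length(core) / observed else 0,
       threshold = as.integer(threshold))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y)`.
#'
#' @param counts samples x taxa matrix.
#' @param zero_policy what to do with a pair of all-zero samples, whose
#'   dissimilarity is undefined: `"error"` (default) or `"one"`.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(counts, zero_policy = c("error", "one")) {
  zero_policy <- match.arg(zero_policy)
  counts <- validate_otu(counts)
  empty <- rowSums(counts) == 0
  if (sum(empty) >= 2L && zero_policy == "error") {
    stop("Bray-Curtis undefined for all-zero sample pairs: ",
         paste(rownames(counts)[empty], collapse = ", "))
  }
  d <- vegan::vegdist(counts, method = "bray")
  if (any(empty)) d[is.nan(d)] <- 1
  d
}

#' Levins niche breadth
#'
#' For taxon j with across-sample proportions `P_jh` (its count in sample h
#' over its total), `B_j = 1 / sum_h P_jh^2`; the community-level value for a
#' sample is the unweighted mean of `B_j` over taxa present in it.  The
#' habitat unit is the individual sample.
#'
#' @param counts samples x taxa matrix.
#' @return list with `per_taxon` (named vector of B_j) and `per_sample`
#'   (named vector of community means B_com).  Taxa with zero total are
#'   excluded with a warning.
#' @export
niche_breadth <- function(counts) {
  counts <- validate_otu(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning("excluding taxa with zero total counts: ",
            paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  keep <- totals > 0
  P <- sweep(counts[, keep, drop = FALSE], 2L, totals[keep], "/")
  B <- 1 / colSums(P^2)
  present <- counts[, keep, drop = FALSE] > 0
  bcom <- apply(present, 1L, function(pr) {
    if (!any(pr)) return(NA_real_)
    mean(B[pr])
  })
  list(per_taxon = B, per_sample = bcom)
}
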