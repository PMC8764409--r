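# PerMANOVA pseudo-F with a label-permutation test, and a multivariate
# regression tree (MRT): greedy binary partitioning of a (Hellinger-
# transformed) community matrix on environmental thresholds, pruned by
# 10-fold cross-validation.

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the squared inter-sample distances:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and
#' `pseudo-F = ((SS_total - SS_within)/(g - 1)) / (SS_within/(n - g))`.
#' The p-value permutes whole group labels and uses the add-one estimator
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`, which can never be zero.
#'
#' @param d `dist` or symmetric matrix of dissimilarities over samples.
#' @param groups group label per sample (>= 2 groups of >= 2 samples).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return object of class `permanova`: list with `F`, `R2`, `p`,
#'   `n_perm`, `group_sizes`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("groups must match the distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 samples each")
  }
  g <- length(sizes)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  if (ss_total == 0) {
    stop("all pairwise distances are zero; pseudo-F is degenerate (0/0)")
  }
  within_ss <- function(lab) {
    s <- 0
    for (l in levels(lab)) {
      m <- lab == l
      s <- s + sum(D2[m, m]) / (2 * sum(m))
    }
    s
  }
  fstat <- function(sw) ((ss_total - sw) / (g - 1)) / (sw / (n - g))
  sw_obs <- within_ss(groups)
  if (sw_obs == 0) {
    # perfect separation: the permutation distribution is uninformative
    warning("within-group sum of squares is zero; pseudo-F infinite")
    return(structure(list(F = Inf, R2 = 1, p = 1 / (1 + n_perm),
                          n_perm = as.integer(n_perm),
                          group_sizes = as.integer(sizes),
                          df = c(between = g - 1L, within = n - g)),
                     class = "permanova"))
  }
  f_obs <- fstat(sw_obs)
  p <- with_seed(seed, {
    hits <- 0L
    for (r in seq_len(n_perm)) {
      f_perm <- fstat(within_ss(sample(groups)))
      if (f_perm >= f_obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  structure(list(F = f_obs, R2 = (ss_total - sw_obs) / ss_total, p = p,
                 n_perm = as.integer(n_perm),
                 group_sizes = as.integer(sizes),
                 df = c(between = g - 1L, within = n - g)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PerMANOVA: pseudo-F(%d, %d) = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$df[["between"]], x$df[["within"]], x$F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Hellinger transform of a count table
#'
#' Square root of within-sample relative abundances; the response geometry
#' under which Euclidean node variance behaves sensibly for community data.
#'
#' @param counts samples x taxa matrix.
#' @return transformed numeric matrix.
#' @export
hellinger <- function(counts) {
  vegan::decostand(validate_otu(counts), method = "hellinger")
}

# --- MRT internals ---------------------------------------------------------

# Residual SS of rows idx of Y about their centroid.
node_ss <- function(Y, idx) {
  if (length(idx) < 2L) return(0)
  sub <- Y[idx, , drop = FALSE]
  sum(sub^2) - sum(colSums(sub)^2) / length(idx)
}

# Best (variable, threshold) split of node rows idx: maximal reduction in
# within-node SS; thresholds are midpoints of consecutive sorted unique
# values; both children must hold >= min_leaf samples.  Deterministic
# tie-break: variable order, then smaller threshold.
best_split <- function(Y, X, idx, min_leaf) {
  n <- length(idx)
  parent <- node_ss(Y, idx)
  best <- NULL
  for (v in colnames(X)) {
    x <- X[idx, v]
    if (length(unique(x)) < 2L) next   # constant variable: skip
    ord <- order(x)
    xs <- x[ord]
    Ys <- Y[idx[ord], , drop = FALSE]
    cq <- cumsum(rowSums(Ys^2))
    cs <- apply(Ys, 2L, cumsum)
    tot_q <- cq[n]
    tot_s <- cs[n, ]
    for (t in seq_len(n - 1L)) {
      if (xs[t] == xs[t + 1L]) next
      if (t < min_leaf || n - t < min_leaf) next
      ssl <- cq[t] - sum(cs[t, ]^2) / t
      ssr <- (tot_q - cq[t]) - sum((tot_s - cs[t, ])^2) / (n - t)
      gain <- parent - ssl - ssr
      thr <- (xs[t] + xs[t + 1L]) / 2
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(var = v, threshold = thr, gain = gain,
                     left = idx[ord[seq_len(t)]],
                     right = idx[ord[(t + 1L):n]])
      }
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# Grow a best-first split sequence.  Returns list(nodes, splits): nodes is a
# list indexed by node id with members/depth/children; splits is a data.frame
# in growth order, so truncating it after k-1 rows yields the nested tree
# with k leaves.
grow_mrt <- function(Y, X, max_leaves, max_depth, min_leaf) {
  nodes <- list(list(id = 1L, depth = 0L, idx = seq_len(nrow(Y)),
                     var = NA_character_, threshold = NA_real_,
                     left = NA_integer_, right = NA_integer_))
  cand <- list()
  splittable <- function(nd) {
    length(nd$idx) >= 2L * min_leaf && nd$depth < max_depth
  }
  if (max_depth > 0L && splittable(nodes[[1L]])) {
    cand[["1"]] <- best_split(Y, X, nodes[[1L]]$idx, min_leaf)
  }
  splits <- data.frame(step = integer(0), node = integer(0),
                       var = character(0), threshold = numeric(0),
                       gain = numeric(0), stringsAsFactors = FALSE)
  leaves <- 1L
  while (leaves < max_leaves) {
    gains <- vapply(cand, function(s) if (is.null(s)) -Inf else s$gain,
                    numeric(1L))
    if (!length(gains) || all(!is.finite(gains))) break
    pick <- names(gains)[which.max(gains)]   # ties: first = smallest node id
    nd_id <- as.integer(pick)
    sp <- cand[[pick]]
    cand[[pick]] <- NULL
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    nodes[[nd_id]]$var <- sp$var
    nodes[[nd_id]]$threshold <- sp$threshold
    nodes[[nd_id]]$left <- lid
    nodes[[nd_id]]$right <- rid
    nodes[[lid]] <- list(id = lid, depth = nodes[[nd_id]]$depth + 1L,
                         idx = sp$left, var = NA_character_,
                         threshold = NA_real_, left = NA_integer_,
                         right = NA_integer_)
    nodes[[rid]] <- list(id = rid, depth = nodes[[nd_id]]$depth + 1L,
                         idx = sp$right, var = NA_character_,
                         threshold = NA_real_, left = NA_integer_,
                         right = NA_integer_)
    splits <- rbind(splits, data.frame(
      step = nrow(splits) + 1L, node = nd_id, var = sp$var,
      threshold = sp$threshold, gain = sp$gain, stringsAsFactors = FALSE))
    for (cid in c(lid, rid)) {
      if (splittable(nodes[[cid]])) {
        cand[[as.character(cid)]] <- best_split(Y, X, nodes[[cid]]$idx,
                                                min_leaf)
      }
    }
    leaves <- leaves + 1L
  }
  list(nodes = nodes, splits = splits)
}

# Route rows of newX through the first n_splits splits; returns leaf node id
# per row.
route_leaf <- function(nodes, splits, n_splits, newX) {
  active <- splits[seq_len(min(n_splits, nrow(splits))), , drop = FALSE]
  split_of <- stats::setNames(seq_len(nrow(active)), active$node)
  vapply(seq_len(nrow(newX)), function(i) {
    id <- 1L
    repeat {
      k <- split_of[as.character(id)]
      if (is.na(k)) return(id)
      nd <- nodes[[id]]
      id <- if (newX[i, nd$var] < nd$threshold) nd$left else nd$right
    }
  }, integer(1L))
}

#' Multivariate regression tree on environmental predictors
#'
#' Greedy binary recursive partitioning of the community matrix (Hellinger-
#' transformed relative abundances by default) choosing at each step the
#' (variable, threshold) pair that maximally reduces the within-node sum of
#' squared deviations about node centroids.  Tree size (number of leaves) is
#' chosen by minimum k-fold cross-validated relative error; the selected tree
#' is refit on the full data.
#'
#' @param counts samples x taxa matrix.
#' @param env environmental data.frame over the samples.
#' @param vars predictor columns of `env` to use (default: all numeric
#'   columns); constant variables are skipped.
#' @param transform `"hellinger"` (default) or `"proportion"`.
#' @param max_depth maximum split depth (0 forces the root-only tree).
#' @param max_leaves cap on the number of leaves grown.
#' @param min_leaf minimum samples per leaf.
#' @param cv_folds cross-validation folds (capped at the sample count);
#'   0 skips pruning and keeps the fully grown tree.
#' @param seed RNG seed for fold assignment.
#' @return object of class `mrt`: `splits` (selected splits in growth
#'   order), `leaf` (leaf id per sample), `size` (number of leaves),
#'   `explained_variance`, `cv` (size, cv_error, se), `transform`.
#' @export
mrt_fit <- function(counts, env, vars = NULL,
                    transform = c("hellinger", "proportion"),
                    max_depth = 5L, max_leaves = 8L, min_leaf = 2L,
                    cv_folds = 10L, seed = NULL) {
  transform <- match.arg(transform)
  counts <- validate_otu(counts)
  check_ids(counts, env = env)
  env <- env[rownames(counts), , drop = FALSE]
  if (is.null(vars)) {
    vars <- colnames(env)[vapply(env, is.numeric, logical(1L))]
  }
  if (!length(vars)) stop("no numeric predictor variables")
  X <- as.matrix(env[, vars, drop = FALSE])
  Y <- if (transform == "hellinger") hellinger(counts) else
    counts / rowSums(counts)
  n <- nrow(Y)
  if (n < 2L * min_leaf) stop("need at least 2 * min_leaf samples")
  ss_total <- node_ss(Y, seq_len(n))

  full <- grow_mrt(Y, X, max_leaves, max_depth, min_leaf)
  k_max <- nrow(full$splits) + 1L

  cv <- NULL
  size <- if (cv_folds < 2L) k_max else 1L
  if (k_max > 1L && cv_folds >= 2L) {
    folds <- with_seed(seed, sample(rep_len(seq_len(min(cv_folds, n)), n)))
    nf <- max(folds)
    err <- matrix(0, nf, k_max)   # test SS per fold per size
    for (f in seq_len(nf)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      fit <- grow_mrt(Y[tr, , drop = FALSE], X[tr, , drop = FALSE],
                      max_leaves, max_depth, min_leaf)
      for (k in seq_len(k_max)) {
        ns <- min(k - 1L, nrow(fit$splits))
        leaf_tr <- route_leaf(fit$nodes, fit$splits, ns,
                              X[tr, , drop = FALSE])
        mu <- rowsum(Y[tr, , drop = FALSE], leaf_tr) /
          as.vector(table(leaf_tr))
        leaf_te <- route_leaf(fit$nodes, fit$splits, ns,
                              X[te, , drop = FALSE])
        err[f, k] <- sum((Y[te, , drop = FALSE] -
                            mu[as.character(leaf_te), , drop = FALSE])^2)
      }
    }
    cv_error <- colSums(err) / ss_total
    se <- apply(err * nf / ss_total, 2L, stats::sd) / sqrt(nf)
    cv <- data.frame(size = seq_len(k_max), cv_error = cv_error, se = se)
    size <- cv$size[which.min(cv$cv_error)]
  }

  n_splits <- size - 1L
  leaf <- route_leaf(full$nodes, full$splits, n_splits, X)
  ss_res <- sum(vapply(split(seq_len(n), leaf),
                       function(ix) node_ss(Y, ix), numeric(1L)))
  structure(list(
    splits = full$splits[seq_len(n_splits), , drop = FALSE],
    all_splits = full$splits,
    nodes = full$nodes,
    leaf = stats::setNames(leaf, rownames(counts)),
    size = as.integer(size),
    explained_variance = if (ss_total > 0) 1 - ss_res / ss_total else 0,
    cv = cv,
    ss_total = ss_total,
    transform = transform
  ), class = "mrt")
}

#' @export
print.mrt <- function(x, ...) {
  cat(sprintf("Multivariate regression tree: %d leaves, %.1f%% variance explained\n",
              x$size, 100 * x$explained_variance))
  if (nrow(x$splits)) {
    for (i in seq_len(nrow(x$splits))) {
      cat(sprintf("  split %d: %s < %.4g (gain %.4g)\n", i, x$splits$var[i],
                  x$splits$threshold[i], x$splits$gain[i]))
    }
  } else {
    cat("  (root only)\n")
  }
  invisible(x)
}
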