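# Graph topology metrics (average degree, density, average path distance,
# modularity) and their standardisation against Erdos-Renyi G(n, m) nulls.

as_unsigned_graph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  stopifnot(inherits(net, "signed_network"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  igraph::V(g)$name <- net$nodes
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(match(net$edges$taxon_a, net$nodes),
                                    match(net$edges$taxon_b, net$nodes)))
  }
  g
}

# Metrics on a plain igraph object.  APD is the mean shortest-path length
# over all pairs inside the largest connected component; modularity comes
# from deterministic greedy (CNM-style) agglomeration.
graph_metrics <- function(g) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  apd <- NA_real_
  if (e > 0L) {
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    apd <- igraph::mean_distance(sub, directed = FALSE)
  }
  qmod <- NA_real_
  if (e > 0L) {
    cl <- igraph::cluster_fast_greedy(g)
    qmod <- max(igraph::modularity(cl))
  }
  c(n_nodes = n, n_edges = e,
    avg_degree = if (n > 0L) 2 * e / n else NA_real_,
    density = if (n > 1L) 2 * e / (n * (n - 1)) else NA_real_,
    apd = apd, modularity = qmod)
}

#' Topology metrics of a co-occurrence network
#'
#' Average degree `2E/N`, density `2E/(N(N-1))`, average path distance
#' (unweighted, over the largest connected component) and modularity Q from
#' deterministic greedy agglomeration.  Edge signs are ignored for topology
#' (metrics describe the unsigned skeleton); sign fractions are reported
#' separately.
#'
#' @param net a `signed_network` or an `igraph` graph (simple, undirected).
#' @return object of class `topology_summary`: named metrics plus sign
#'   fractions when available.
#' @export
topology_metrics <- function(net) {
  g <- as_unsigned_graph(net)
  if (igraph::vcount(g) < 2L) stop("network needs at least 2 nodes")
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    stop("network must be a simple graph")
  }
  metrics <- graph_metrics(g)
  out <- list(metrics = metrics,
              positive_fraction = if (inherits(net, "signed_network"))
                net$positive_fraction else NA_real_,
              null = NULL)
  class(out) <- "topology_summary"
  out
}

#' Erdos-Renyi G(n, m) null distributions for topology metrics
#'
#' Samples `n_reps` uniform random simple graphs with exactly the observed
#' numbers of nodes and edges, recomputes every metric, and standardises the
#' observed values: `z = (obs - null mean) / null SD` and an empirical
#' two-sided p-value with the add-one estimator.  Metrics that are fixed by
#' construction (density, average degree) have null SD 0 and report `z = NA`
#' with a warning.
#'
#' @param obs a `topology_summary` from [topology_metrics()].
#' @param n_reps number of random graphs.
#' @param seed RNG seed.
#' @return the `topology_summary` with a `null` data.frame added (metric,
#'   null_mean, null_sd, z, p).
#' @export
er_null <- function(obs, n_reps = 1000L, seed = NULL) {
  stopifnot(inherits(obs, "topology_summary"))
  n <- obs$metrics[["n_nodes"]]
  m <- obs$metrics[["n_edges"]]
  if (m > n * (n - 1) / 2) stop("more edges than a simple graph allows")
  keep <- c("avg_degree", "density", "apd", "modularity")
  nulls <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      graph_metrics(igraph::sample_gnm(n, m))[keep]
    }, numeric(length(keep))))
  })
  null_mean <- colMeans(nulls, na.rm = TRUE)
  null_sd <- apply(nulls, 2L, stats::sd, na.rm = TRUE)
  ov <- obs$metrics[keep]
  z <- ifelse(null_sd > 0, (ov - null_mean) / null_sd, NA_real_)
  if (any(null_sd == 0)) {
    warning("degenerate null (SD = 0) for: ",
            paste(keep[null_sd == 0], collapse = ", "))
  }
  pvals <- vapply(seq_along(keep), function(k) {
    dev <- abs(nulls[, k] - null_mean[k])
    (1 + sum(dev >= abs(ov[k] - null_mean[k]), na.rm = TRUE)) / (1 + n_reps)
  }, numeric(1L))
  obs$null <- data.frame(metric = keep, obs = as.numeric(ov),
                         null_mean = as.numeric(null_mean),
                         null_sd = as.numeric(null_sd),
                         z = as.numeric(z), p = pvals,
                         stringsAsFactors = FALSE, row.names = NULL)
  obs$n_reps <- as.integer(n_reps)
  obs
}

#' @export
print.topology_summary <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Topology: %d nodes, %d edges, avgK = %.3f, density = %.4f\n",
    m[["n_nodes"]], m[["n_edges"]], m[["avg_degree"]], m[["density"]]))
  cat(sprintf("  APD = %.3f, modularity Q = %.3f\n",
              m[["apd"]], m[["modularity"]]))
  if (!is.null(x$null)) {
    cat("  Erdos-Renyi null (", x$n_reps, " reps):\n", sep = "")
    print(x$null, digits = 3)
  }
  invisible(x)
}
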