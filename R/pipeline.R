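# Orchestration of the full study workflow: simulate or load inputs, rarefy,
# alpha diversity and core occupancy, Bray-Curtis + PerMANOVA, MRT, betaNTI
# with process classification, Levins niche breadth, Kruskal-Wallis and
# Spearman summaries, ensemble network inference and topology nulls -- with
# derived per-stage seeds and a machine-readable JSON run report.

#' Build a pipeline configuration
#'
#' Either file inputs (`otu_path`, `env_path`, `tree_path`) or a simulation
#' specification (`simulate = list(...)` arguments for
#' [simulate_dataset()]).  All resampling efforts and the master seed live
#' here; per-stage seeds are derived from the master seed by stage name, so
#' any stage can be rerun in isolation.
#'
#' @param out_dir output directory for stage files and the report.
#' @param seed master seed.
#' @param otu_path,env_path,tree_path input files (TSV/TSV/Newick).
#' @param simulate list of [simulate_dataset()] arguments, or `NULL`.
#' @param rarefy_depth `"min"` (rarefy to the minimum sample total) or an
#'   integer depth.
#' @param n_perm PerMANOVA/Mantel permutations.
#' @param n_null betaNTI randomizations.
#' @param net_n_perm,net_n_boot network permutation/bootstrap effort.
#' @param min_occupancy network occupancy threshold.
#' @param n_top,n_bottom candidate ranking depth.
#' @param alpha FDR level for edge acceptance.
#' @param er_reps Erdos-Renyi null replicates.
#' @param run_network,run_mrt stage switches.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            otu_path = NULL, env_path = NULL,
                            tree_path = NULL, simulate = NULL,
                            rarefy_depth = "min",
                            n_perm = 999L, n_null = 999L,
                            net_n_perm = 1000L, net_n_boot = 1000L,
                            min_occupancy = 0.8, n_top = 500L,
                            n_bottom = 500L, alpha = 0.05,
                            er_reps = 1000L, run_network = TRUE,
                            run_mrt = TRUE) {
  counts_ok <- all(c(n_perm, n_null, net_n_perm, net_n_boot, er_reps) > 0)
  if (!counts_ok) stop("all resampling counts must be positive")
  if (is.null(simulate) &&
      (is.null(otu_path) || is.null(env_path) || is.null(tree_path))) {
    stop("provide either input paths or a simulation spec")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 otu_path = otu_path, env_path = env_path,
                 tree_path = tree_path, simulate = simulate,
                 rarefy_depth = rarefy_depth, n_perm = as.integer(n_perm),
                 n_null = as.integer(n_null),
                 net_n_perm = as.integer(net_n_perm),
                 net_n_boot = as.integer(net_n_boot),
                 min_occupancy = min_occupancy, n_top = as.integer(n_top),
                 n_bottom = as.integer(n_bottom), alpha = alpha,
                 er_reps = as.integer(er_reps),
                 run_network = isTRUE(run_network),
                 run_mrt = isTRUE(run_mrt)),
            class = "pipeline_config")
}

stage_log <- function(quiet, ...) if (!quiet) message("[salinet] ", ...)

#' Kruskal-Wallis group tests and metric-environment correlations
#'
#' Kruskal-Wallis test of each metric across groups, and Spearman
#' correlations of each metric against each environmental variable, with
#' conventional significance stars at 0.05/0.01/0.001.
#'
#' @param metrics data.frame of per-sample metrics (rows = samples).
#' @param env environmental data.frame over the same samples; its numeric
#'   columns are the correlates.
#' @param groups group label per sample (>= 2 groups).
#' @return list with `kruskal` (metric, statistic, p) and `correlations`
#'   (metric, variable, rho, p, stars).
#' @export
kruskal_and_correlations <- function(metrics, env, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  stars <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                    ifelse(p < 0.05, "*", "ns")))
  }
  kw <- do.call(rbind, lapply(colnames(metrics), function(mv) {
    x <- metrics[[mv]]
    kt <- suppressWarnings(stats::kruskal.test(x, groups))
    data.frame(metric = mv, statistic = unname(kt$statistic),
               p = kt$p.value, stringsAsFactors = FALSE)
  }))
  numvars <- colnames(env)[vapply(env, is.numeric, logical(1L))]
  cors <- do.call(rbind, lapply(colnames(metrics), function(mv) {
    do.call(rbind, lapply(numvars, function(ev) {
      ct <- suppressWarnings(
        stats::cor.test(metrics[[mv]], env[[ev]], method = "spearman"))
      data.frame(metric = mv, variable = ev,
                 rho = unname(ct$estimate), p = ct$p.value,
                 stars = stars(ct$p.value), stringsAsFactors = FALSE)
    }))
  }))
  list(kruskal = kw, correlations = cors)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, rarefaction, alpha diversity + Core100/Core80,
#' Bray-Curtis + PerMANOVA, the multivariate regression tree, the betaNTI
#' null model with process classification, Levins niche breadth,
#' Kruskal-Wallis/Spearman summaries, ensemble network inference and
#' Erdos-Renyi topology nulls, writing every stage output plus a JSON run
#' report to `config$out_dir`.  The same config and seed reproduce the
#' report byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the run report (named list), invisibly; written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(schema_version = "1.0", seed = config$seed)

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    stage_log(quiet, "simulating synthetic data set")
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% derive_seed(config$seed, "simulate")
    sim <- do.call(simulate_dataset, sim_args)
    otu <- sim$otu; env <- sim$env; tree <- sim$tree
    write_otu_table(otu, out("otu_table.tsv"))
    write_env_table(env, out("env.tsv"))
    ape::write.tree(tree, out("tree.nwk"))
    jsonlite::write_json(list(design = sim$truth$design,
                              niche = sim$truth$niche,
                              pairs = sim$truth$pairs,
                              bm_rate = sim$truth$bm_rate),
                         out("truth.json"), auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stage_log(quiet, "loading inputs")
    otu <- read_otu_table(config$otu_path)
    env <- read_env_table(config$env_path)
    tree <- read_tree(config$tree_path)
  }
  check_ids(otu, tree = tree, env = env)
  env <- env[rownames(otu), , drop = FALSE]
  groups <- env$group
  if (is.null(groups)) stop("environmental table must carry a 'group' column")

  # --- rarefaction ----------------------------------------------------------
  depth <- if (identical(config$rarefy_depth, "min")) min(rowSums(otu)) else
    as.integer(config$rarefy_depth)
  stage_log(quiet, "rarefying to depth ", depth)
  rare <- rarefy_counts(otu, depth = depth,
                        seed = derive_seed(config$seed, "rarefy"),
                        drop_empty = TRUE)
  report$rarefaction_depth <- as.integer(depth)

  # --- alpha diversity, core, niche breadth ---------------------------------
  stage_log(quiet, "alpha diversity, core community, niche breadth")
  alpha <- alpha_diversity(rare)
  utils::write.table(alpha, out("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  core100 <- core_fraction(rare, 1.0)
  core80 <- core_fraction(rare, 0.8)
  nb <- niche_breadth(rare)
  by_group <- function(x) {
    v <- tapply(x, groups, mean)
    as.list(stats::setNames(as.numeric(v), names(v)))
  }
  report$alpha <- list(richness_mean = by_group(alpha$richness),
                       shannon_mean = by_group(alpha$shannon),
                       simpson_mean = by_group(alpha$simpson))
  report$core <- list(core100_fraction = core100$fraction,
                      core80_fraction = core80$fraction)
  report$niche_breadth_mean <- by_group(nb$per_sample)

  # --- Bray-Curtis + PerMANOVA ---------------------------------------------
  stage_log(quiet, "Bray-Curtis and PerMANOVA")
  bc <- bray_curtis(rare)
  pmv <- permanova(bc, groups, n_perm = config$n_perm,
                   seed = derive_seed(config$seed, "permanova"))
  report$permanova <- list(pseudo_F = pmv$F, R2 = pmv$R2, p = pmv$p,
                           n_perm = pmv$n_perm)

  # --- MRT ------------------------------------------------------------------
  if (config$run_mrt) {
    stage_log(quiet, "multivariate regression tree")
    mrt <- mrt_fit(rare, env, seed = derive_seed(config$seed, "mrt"))
    utils::write.table(
      data.frame(sample_id = names(mrt$leaf), leaf = mrt$leaf),
      out("mrt_leaves.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    report$mrt <- list(
      size = mrt$size,
      explained_variance = mrt$explained_variance,
      splits = if (nrow(mrt$splits)) {
        lapply(seq_len(nrow(mrt$splits)), function(i) {
          list(var = mrt$splits$var[i],
               threshold = mrt$splits$threshold[i])
        })
      } else list()
    )
  }

  # --- betaNTI --------------------------------------------------------------
  stage_log(quiet, "betaNTI null model (", config$n_null, " randomizations)")
  bn <- suppressWarnings(
    bnti(rare, tree, n_null = config$n_null,
         seed = derive_seed(config$seed, "bnti")))
  utils::write.table(bn$pairs, out("bnti_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ga <- groups[match(bn$pairs$sample_a, rownames(otu))]
  gb <- groups[match(bn$pairs$sample_b, rownames(otu))]
  within <- bn$pairs[ga == gb, ]
  wg <- ga[ga == gb]
  med <- tapply(within$bnti, wg, stats::median, na.rm = TRUE)
  frac <- function(cls) {
    v <- tapply(within$class == cls, wg, mean, na.rm = TRUE)
    as.list(stats::setNames(as.numeric(v), names(v)))
  }
  report$bnti <- list(
    n_null = bn$n_null,
    within_group_median = as.list(stats::setNames(as.numeric(med),
                                                  names(med))),
    fraction_homogeneous_selection = frac("homogeneous_selection"),
    fraction_variable_selection = frac("variable_selection"),
    fraction_stochastic = frac("stochastic")
  )

  # --- phylogenetic signal --------------------------------------------------
  stage_log(quiet, "phylogenetic signal (Mantel)")
  ps <- phylo_signal(tree, rare, env, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, "mantel"))
  report$phylo_signal <- list(mantel_r = ps$r, p = ps$p)

  # --- group tests and correlations ----------------------------------------
  met <- data.frame(shannon = alpha$shannon, simpson = alpha$simpson,
                    richness = alpha$richness,
                    niche_breadth = as.numeric(nb$per_sample))
  kc <- kruskal_and_correlations(met, env, groups)
  utils::write.table(kc$correlations, out("correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$kruskal <- lapply(seq_len(nrow(kc$kruskal)), function(i) {
    list(metric = kc$kruskal$metric[i], p = kc$kruskal$p[i])
  })

  # --- network + topology ---------------------------------------------------
  if (config$run_network) {
    stage_log(quiet, "ensemble co-occurrence network")
    net <- infer_network(rare, min_occupancy = config$min_occupancy,
                         n_top = config$n_top, n_bottom = config$n_bottom,
                         n_perm = config$net_n_perm,
                         n_boot = config$net_n_boot,
                         alpha = config$alpha,
                         seed = derive_seed(config$seed, "network"))
    write_network(net, out("network_edges.tsv"), format = "tsv")
    write_network(net, out("network.graphml"), format = "graphml")
    report$network <- list(
      n_nodes = length(net$nodes),
      n_edges = nrow(net$edges),
      positive_fraction = net$positive_fraction,
      negative_fraction = if (nrow(net$edges))
        1 - net$positive_fraction else NA,
      discarded_tie = net$discarded_tie,
      n_candidates = net$n_candidates
    )
    if (length(net$nodes) >= 2L && nrow(net$edges) >= 1L) {
      stage_log(quiet, "topology metrics and Erdos-Renyi null")
      topo <- topology_metrics(net)
      topo <- suppressWarnings(
        er_null(topo, n_reps = config$er_reps,
                seed = derive_seed(config$seed, "er_null")))
      report$topology <- list(
        avg_degree = topo$metrics[["avg_degree"]],
        density = topo$metrics[["density"]],
        apd = topo$metrics[["apd"]],
        modularity = topo$metrics[["modularity"]],
        er_z = as.list(stats::setNames(topo$null$z, topo$null$metric)),
        er_p = as.list(stats::setNames(topo$null$p, topo$null$metric))
      )
    }
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null")
  stage_log(quiet, "report written to ", out("report.json"))
  invisible(report)
}
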