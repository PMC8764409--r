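# Readers/writers for the external representations the pipeline touches:
# OTU count tables and environmental tables (TSV), phylogenies (Newick),
# and signed networks (edge-list TSV / GraphML).  The internal canonical
# orientation for count tables is samples x taxa.

#' Validate an OTU count table
#'
#' Checks the invariants every analysis entry point relies on: a numeric
#' matrix of non-negative integer counts with unique, non-empty sample
#' (row) and taxon (column) identifiers, and at least 2 samples and 2 taxa.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames.
#' @return the validated matrix (storage mode integer-valued numeric),
#'   invisibly usable anywhere an OTU table is expected.
#' @export
validate_otu <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("OTU table must be a numeric matrix (samples x taxa)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("OTU table must carry sample (row) and taxon (column) names")
  }
  rownames(counts) <- trim_ids(rownames(counts))
  colnames(counts) <- trim_ids(colnames(counts))
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("OTU table needs at least 2 samples and 2 taxa")
  }
  if (anyNA(counts)) stop("OTU table contains missing values")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  counts
}

#' Read an OTU count table from TSV
#'
#' @param path TSV file with one header row and the first column holding
#'   identifiers.
#' @param orientation `"samples"` if samples are rows in the file (the
#'   canonical form), `"taxa"` if taxa are rows; the returned matrix is
#'   always samples x taxa.
#' @return integer count matrix, samples x taxa.
#' @export
read_otu_table <- function(path, orientation = c("samples", "taxa")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- trim_ids(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop(sprintf("non-numeric cell in column '%s', row '%s'",
                   colnames(body)[j], ids[bad %||% 1L]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  colnames(m) <- trim_ids(colnames(m))
  if (orientation == "taxa") m <- t(m)
  validate_otu(m)
}

#' Write an OTU count table to TSV
#'
#' @param counts samples x taxa matrix.
#' @param path output file.
#' @param orientation row entity written to the file.
#' @export
write_otu_table <- function(counts, path, orientation = c("samples", "taxa")) {
  orientation <- match.arg(orientation)
  m <- validate_otu(counts)
  if (orientation == "taxa") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- if (orientation == "samples") "sample_id" else "taxon_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample environmental metadata from TSV
#'
#' First column holds sample identifiers; remaining columns are environmental
#' variables (numeric) and optionally a categorical `group` label.
#'
#' @param path TSV file.
#' @return data.frame with sample identifiers as row names.
#' @export
read_env_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- trim_ids(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if ("salinity" %in% colnames(df)) {
    if (!is.numeric(df$salinity)) stop("salinity must be numeric")
    if (any(df$salinity < 0, na.rm = TRUE)) stop("salinity must be >= 0")
  }
  df
}

#' Write environmental metadata to TSV
#' @param env data.frame with sample ids as row names.
#' @param path output file.
#' @export
write_env_table <- function(env, path) {
  df <- data.frame(sample_id = rownames(env), env, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Newick file.
#' @param missing_lengths `"error"` (strict; the default, because phylogenetic
#'   turnover metrics are meaningless with silently defaulted lengths) or
#'   `"zero"` to coerce absent branch lengths to 0.
#' @return an [ape::read.tree()] `phylo` object with trimmed tip labels.
#' @export
read_tree <- function(path, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick file: ", path)
  tree$tip.label <- trim_ids(tree$tip.label)
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "error") stop("tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (missing_lengths == "error") {
      stop("tree has missing branch lengths on ",
           sum(is.na(tree$edge.length)), " edges")
    }
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Check identifier agreement between a table, a tree and metadata
#'
#' Every taxon of the table must appear exactly once as a tree tip, and the
#' environmental table must cover every sample.  Errors list the offending
#' identifiers.
#'
#' @param counts samples x taxa matrix.
#' @param tree optional `phylo`.
#' @param env optional environmental data.frame (sample ids as row names).
#' @return `TRUE` invisibly.
#' @export
check_ids <- function(counts, tree = NULL, env = NULL) {
  counts <- validate_otu(counts)
  if (!is.null(tree)) {
    missing <- setdiff(colnames(counts), tree$tip.label)
    if (length(missing)) {
      stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
    }
    if (anyDuplicated(tree$tip.label)) {
      stop("duplicated tree tips: ",
           paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                 collapse = ", "))
    }
  }
  if (!is.null(env)) {
    missing <- setdiff(rownames(counts), rownames(env))
    if (length(missing)) {
      stop("samples absent from the environmental table: ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Write a signed co-occurrence network
#'
#' Edge-list TSV columns: `taxon_a`, `taxon_b`, `sign`,
#' `n_supporting_measures`, `merged_p`, `q`.  GraphML carries the same edge
#' attributes.  An empty network writes a header-only TSV.
#'
#' @param net a `signed_network` (see [finalize_network()]).
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "signed_network"))
  cols <- c("taxon_a", "taxon_b", "sign", "n_supporting_measures",
            "merged_p", "q")
  edges <- net$edges[, cols, drop = FALSE]
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
    if (nrow(edges)) {
      g <- igraph::add_edges(g, rbind(match(edges$taxon_a, net$nodes),
                                      match(edges$taxon_b, net$nodes)))
      igraph::E(g)$sign <- edges$sign
      igraph::E(g)$n_supporting_measures <- edges$n_supporting_measures
      igraph::E(g)$merged_p <- edges$merged_p
      igraph::E(g)$q <- edges$q
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a signed network back from an edge-list TSV or GraphML file
#'
#' @param path input file.
#' @param format `"tsv"` or `"graphml"`.
#' @param nodes optional full node set (isolated nodes are not represented in
#'   a TSV edge list).
#' @return a `signed_network`.
#' @export
read_network <- function(path, format = c("tsv", "graphml"), nodes = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (is.null(nodes)) nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    el <- igraph::as_edgelist(g)
    edges <- data.frame(
      taxon_a = el[, 1L], taxon_b = el[, 2L],
      sign = if (igraph::ecount(g)) igraph::E(g)$sign else character(0),
      n_supporting_measures =
        if (igraph::ecount(g)) igraph::E(g)$n_supporting_measures else integer(0),
      merged_p = if (igraph::ecount(g)) igraph::E(g)$merged_p else numeric(0),
      q = if (igraph::ecount(g)) igraph::E(g)$q else numeric(0),
      stringsAsFactors = FALSE
    )
  }
  new_signed_network(edges, nodes)
}
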