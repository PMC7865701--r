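#' Build the SC interaction network
#'
#' Genes are nodes, SC pairs undirected edges. Duplicate pairs (in either
#' orientation) collapse to a single edge; self-pairs are rejected.
#'
#' @param pairs An `sc_screen` object (its declared SC pairs are used) or a
#'   `data.frame` with `gene_a`, `gene_b` columns.
#' @return An [igraph::igraph] undirected simple graph with nodes in sorted
#'   symbol order.
#' @export
build_sc_network <- function(pairs) {
  if (inherits(pairs, "sc_screen")) pairs <- sc_pairs(pairs)
  if (nrow(pairs) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  if (any(pairs$gene_a == pairs$gene_b))
    stop("self-pairs (gene_a == gene_b) are not valid SC edges")
  nodes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Summarise an SC network
#'
#' @param net An igraph graph.
#' @param n_top Number of highest-degree nodes to report.
#' @return A list of class `sc_network_summary` with `n_nodes`, `n_edges`,
#'   `average_degree` (2E/N; 0 for the empty graph), `connected_components`
#'   and `top_degree_nodes` (named degree vector, decreasing).
#' @export
network_summary <- function(net, n_top = 5L) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  deg <- igraph::degree(net)
  top <- if (n > 0L) sort(deg, decreasing = TRUE)[seq_len(min(n_top, n))] else deg
  structure(list(n_nodes = n, n_edges = e,
                 average_degree = if (n > 0L) 2 * e / n else 0,
                 connected_components = igraph::components(net)$no,
                 top_degree_nodes = top),
            class = "sc_network_summary")
}

#' @export
print.sc_network_summary <- function(x, ...) {
  cat("SC network: ", x$n_nodes, " nodes, ", x$n_edges, " edges, ",
      x$connected_components, " components\n", sep = "")
  cat("  average degree: ", format(round(x$average_degree, 3), nsmall = 3),
      "\n", sep = "")
  if (length(x$top_degree_nodes) > 0L)
    cat("  top degrees: ",
        paste(names(x$top_degree_nodes), x$top_degree_nodes,
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Louvain community detection
#'
#' Greedy two-phase modularity maximisation. The sweep order inside the
#' Louvain procedure is randomised, so the run is made reproducible by
#' seeding R's RNG with `seed` before the call.
#'
#' @param net A non-empty igraph graph.
#' @param seed Integer RNG seed for reproducibility.
#' @param resolution Modularity resolution parameter.
#' @return A list with `membership` (named integer labels), `modularity`
#'   (score of the returned partition) and `n_communities`.
#' @export
detect_communities <- function(net, seed = 1L, resolution = 1.0) {
  if (igraph::vcount(net) == 0L) stop("network is empty")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cl <- igraph::cluster_louvain(net, resolution = resolution)
  mem <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(mem),
                                    igraph::V(net)$name),
       modularity = igraph::modularity(net, mem),
       n_communities = length(unique(mem)))
}

#' Export / import an SC network
#'
#' `graphml` writes GraphML with `degree` and (when supplied) `community`
#' node attributes; `edge_tsv` writes a two-column edge table. Both round
#' trip losslessly through [import_network()] for the node and edge sets.
#'
#' @param net An igraph graph.
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param communities Optional membership vector (as from
#'   [detect_communities()]) stored as a node attribute in GraphML.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_tsv"),
                           communities = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net
    igraph::V(g)$degree <- igraph::degree(g)
    if (!is.null(communities))
      igraph::V(g)$community <- as.integer(communities[igraph::V(g)$name])
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2],
                                  stringsAsFactors = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @return `import_network()` returns the igraph graph read back from disk.
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    build_sc_network(df)
  }
}
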