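#' Construct a MicrobialNetwork
#'
#' Undirected signed weighted network over taxa (optionally site-tagged for
#' cross-site mode). Each retained pair appears once in the edge list.
#'
#' @param nodes `data.frame` with at least a `node` column; optional `site`,
#'   `mean_abund`, `phylum` annotation columns.
#' @param edges `data.frame` with columns `from`, `to`, `rho`, `p`. A `sign`
#'   column is derived from `rho`.
#' @return Object of class `microbial_network` with node/edge tables, per-node
#'   degrees and summary stats (largest-component average shortest path,
#'   positive:negative edge ratio).
#' @export
microbial_network <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes)
  if (!"node" %in% names(nodes)) stop("nodes needs a 'node' column")
  if (anyDuplicated(nodes$node)) stop("duplicate node identifiers")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), p = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges)
    req <- c("from", "to", "rho", "p")
    if (!all(req %in% names(edges)))
      stop("edges needs columns: ", paste(req, collapse = ", "))
    if (any(is.na(edges$p)))
      stop("edges with missing p; run significance testing before building")
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    bad <- setdiff(c(edges$from, edges$to), nodes$node)
    if (length(bad) > 0) stop("edge endpoints not in node set: ",
                              paste(bad, collapse = ", "))
    key <- apply(cbind(pmin(edges$from, edges$to), pmax(edges$from, edges$to)),
                 1, paste, collapse = "\r")
    if (anyDuplicated(key)) stop("duplicate edges (each pair may appear once)")
    edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = nodes$node)
  nodes$degree <- as.numeric(igraph::degree(g))[match(nodes$node, igraph::V(g)$name)]
  comp <- igraph::components(g)
  lcc <- which(comp$membership == which.max(comp$csize))
  apl <- if (length(lcc) >= 2) {
    igraph::mean_distance(igraph::induced_subgraph(g, lcc), directed = FALSE)
  } else NA_real_
  n_pos <- sum(edges$sign == "positive")
  n_neg <- sum(edges$sign == "negative")
  structure(list(
    nodes = nodes, edges = edges,
    stats = list(n_nodes = nrow(nodes), n_edges = nrow(edges),
                 lcc_size = if (nrow(nodes)) max(comp$csize) else 0L,
                 avg_path_length = apl,
                 n_positive = n_pos, n_negative = n_neg,
                 pos_neg_ratio = if (n_neg > 0) n_pos / n_neg else NA_real_)
  ), class = "microbial_network")
}

#' @export
print.microbial_network <- function(x, ...) {
  cat(sprintf("<microbial_network> %d nodes, %d edges (%d +, %d -), LCC %d\n",
              x$stats$n_nodes, x$stats$n_edges, x$stats$n_positive,
              x$stats$n_negative, x$stats$lcc_size))
  invisible(x)
}

#' Convert a MicrobialNetwork to an igraph object
#' @param net a `microbial_network`.
#' @return igraph graph with node and edge attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param net a `microbial_network` (edges must carry p-values).
#' @param path output stem; writes `<path>.edges.tsv` and `<path>.graphml`.
#' @return Invisibly, the two file paths.
#' @export
write_network <- function(net, path) {
  edge_path <- paste0(path, ".edges.tsv")
  gml_path <- paste0(path, ".graphml")
  cols <- c("from", "to", "rho", "p", "sign")
  write.table(net$edges[, cols, drop = FALSE], edge_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(as_igraph(net), gml_path, format = "graphml")
  invisible(c(edges = edge_path, graphml = gml_path))
}

#' Read a network from an edge-list TSV
#'
#' @param edge_path edge-list TSV written by [write_network()].
#' @param nodes optional node `data.frame`; defaults to the endpoints present
#'   in the edge list.
#' @return A `microbial_network`.
#' @export
read_network <- function(edge_path, nodes = NULL) {
  edges <- read.delim(edge_path, stringsAsFactors = FALSE)
  if (is.null(nodes)) {
    nodes <- data.frame(node = sort(unique(c(edges$from, edges$to))),
                        stringsAsFactors = FALSE)
  }
  microbial_network(nodes, edges)
}
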