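#' Construct a protein-association graph
#'
#' Undirected graph with per-edge confidence scores and a role per node
#' (`seed`, `shell1` or `shell2`). Self-loops are forbidden; duplicate
#' unordered edges are forbidden.
#'
#' @param nodes data.frame with columns `node`, `role` (or a character vector
#'   of node names, all given role `"seed"`).
#' @param edges data.frame with columns `from`, `to`, `confidence`.
#' @return a `ppa_graph` object (list with `nodes`, `edges`).
#' @export
ppa_graph <- function(nodes, edges = NULL) {
  if (is.character(nodes))
    nodes <- data.frame(node = nodes, role = "seed")
  nodes$node <- as.character(nodes$node)
  if (!"role" %in% names(nodes)) nodes$role <- "seed"
  if (anyDuplicated(nodes$node))
    gp_stop("duplicated node: ", nodes$node[duplicated(nodes$node)][1])
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        confidence = numeric())
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) gp_stop("self-loops are not allowed")
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$node)
  if (length(missing_ep))
    gp_stop("edge endpoint not in node table: ", missing_ep[1])
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) gp_stop("duplicate edge: ", key[duplicated(key)][1])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes[c("node", "role")],
                 edges = edges[c("from", "to", "confidence")]),
            class = "ppa_graph")
}

#' @export
print.ppa_graph <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = c("seed", "shell1", "shell2")))
  cat("ppa_graph:", nrow(x$nodes), "nodes (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a ppa_graph to an igraph object
#' @param g a `ppa_graph`.
#' @return an undirected [igraph::graph] with edge attribute `confidence`
#'   (also copied to `weight`) and vertex attribute `role`.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes)
  if (nrow(g$edges))
    igraph::E(ig)$weight <- igraph::E(ig)$confidence
  ig
}

#' Write a ppa_graph as a pair of TSV tables
#' @param g a `ppa_graph`.
#' @param edge_path path of the edge-list TSV (`from`, `to`, `confidence`).
#' @param node_path optional path of the node-role TSV.
#' @return `edge_path`, invisibly.
#' @export
write_ppa_graph <- function(g, edge_path, node_path = NULL) {
  write.table(g$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(node_path))
    write.table(g$nodes, node_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(edge_path)
}
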