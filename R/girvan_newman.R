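#' Girvan-Newman edge-betweenness community detection
#'
#' Repeatedly removes the edge with maximal edge betweenness (recomputed
#' after every removal; ties broken by lexicographic endpoint pair) and
#' returns the partition along the removal sequence that maximizes the
#' Newman-Girvan modularity of the original graph. Edgeless input yields
#' singleton clusters; communities never span disconnected components.
#'
#' @param g a `ppa_graph`.
#' @return list with `membership` (named integer vector, cluster ids 1-based
#'   numbered by lexicographically first member), `n_clusters` and
#'   `modularity` of the returned partition.
#' @export
edge_betweenness_communities <- function(g) {
  nodes <- g$nodes$node
  n <- length(nodes)
  if (n == 0) gp_stop("empty graph")
  ig0 <- as_igraph(g)
  ig <- ig0
  comp_membership <- function(graph) {
    igraph::components(graph)$membership[nodes]
  }
  if (igraph::ecount(ig0) == 0) {
    membership <- canonical_membership(seq_len(n), nodes)
    return(list(membership = membership, n_clusters = n, modularity = 0))
  }
  best_m <- comp_membership(ig)
  best_q <- igraph::modularity(ig0, best_m)
  while (igraph::ecount(ig) > 0) {
    eb <- igraph::edge_betweenness(ig, directed = FALSE, weights = NA)
    ends <- igraph::as_edgelist(ig)
    lo <- pmin(ends[, 1], ends[, 2]); hi <- pmax(ends[, 1], ends[, 2])
    pick <- order(-eb, lo, hi)[1]
    ig <- igraph::delete_edges(ig, pick)
    m <- comp_membership(ig)
    q <- igraph::modularity(ig0, m)
    if (q > best_q + 1e-12) { best_q <- q; best_m <- m }
  }
  membership <- canonical_membership(best_m, nodes)
  list(membership = membership, n_clusters = max(membership),
       modularity = best_q)
}

# renumber cluster ids 1..k by each cluster's lexicographically first member
canonical_membership <- function(m, nodes) {
  m <- as.integer(factor(m))
  firsts <- vapply(split(nodes, m), function(v) sort(v)[1], "")
  relabel <- order(order(firsts))
  out <- relabel[m]
  names(out) <- nodes
  out
}
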