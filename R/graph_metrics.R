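#' Degree centrality
#'
#' Fraction of other nodes each node touches: `deg(v) / (n - 1)` on the
#' unweighted topology.
#'
#' @param g a `ppa_graph`.
#' @return named numeric vector over nodes.
#' @export
degree_centrality <- function(g) {
  n <- nrow(g$nodes)
  if (n < 2) {
    warning("degree centrality undefined on a single-node graph; returning 0",
            call. = FALSE)
    return(setNames(rep(0, n), g$nodes$node))
  }
  ig <- as_igraph(g)
  setNames(igraph::degree(ig) / (n - 1), igraph::V(ig)$name)[g$nodes$node]
}

#' Latora harmonic closeness centrality
#'
#' `C(v) = (1/(n-1)) * sum over u != v of 1/d(u, v)` with unweighted
#' shortest-path distances and `1/Inf = 0`, so disconnected node pairs
#' contribute nothing. Set `normalized = FALSE` for the raw reciprocal-
#' distance sum.
#'
#' @param g a `ppa_graph`.
#' @param normalized divide by `n - 1` (default `TRUE`).
#' @return named numeric vector over nodes.
#' @export
harmonic_closeness <- function(g, normalized = TRUE) {
  n <- nrow(g$nodes)
  if (n < 2) return(setNames(rep(0, n), g$nodes$node))
  ig <- as_igraph(g)
  h <- igraph::harmonic_centrality(ig, weights = NA, normalized = FALSE)
  if (normalized) h <- h / (n - 1)
  setNames(h, igraph::V(ig)$name)[g$nodes$node]
}

#' Betweenness centrality
#'
#' Fraction of shortest paths passing through each node, summed over
#' unordered pairs `s != t != v` and normalized by `(n-1)(n-2)/2`; pairs in
#' different components contribute 0. Unweighted topology.
#'
#' @param g a `ppa_graph`.
#' @param normalized normalize by `(n-1)(n-2)/2` (default `TRUE`).
#' @return named numeric vector over nodes.
#' @export
betweenness_centrality <- function(g, normalized = TRUE) {
  n <- nrow(g$nodes)
  if (n < 3) return(setNames(rep(0, n), g$nodes$node))
  ig <- as_igraph(g)
  b <- igraph::betweenness(ig, directed = FALSE, weights = NA,
                           normalized = normalized)
  setNames(b, igraph::V(ig)$name)[g$nodes$node]
}

#' Centrality weights for the combined node score
#'
#' @param w_deg,w_clo,w_bet non-negative weights for degree, harmonic
#'   closeness and betweenness; must sum to 1. Defaults 0.2 / 0.3 / 0.5.
#' @return list of the three weights.
#' @export
score_weights <- function(w_deg = 0.2, w_clo = 0.3, w_bet = 0.5) {
  w <- c(w_deg, w_clo, w_bet)
  if (any(w < 0)) gp_stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) gp_stop("weights must sum to 1")
  list(w_deg = w_deg, w_clo = w_clo, w_bet = w_bet)
}

minmax_rescale <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' Weighted combined centrality score per node
#'
#' Computes the three centralities, min-max rescales each across nodes to
#' `[0, 1]` (a constant column rescales to 0), and combines them as
#' `w_deg * deg + w_clo * clo + w_bet * bet` (defaults 0.2 / 0.3 / 0.5).
#' Set `rescale = FALSE` to weight the raw normalized centralities instead.
#'
#' @param g a `ppa_graph`.
#' @param weights a [score_weights()] list.
#' @param rescale min-max rescale each centrality before weighting.
#' @return data.frame with columns `node`, `c_deg`, `c_clo`, `c_bet`,
#'   `combined`.
#' @export
combined_score <- function(g, weights = score_weights(), rescale = TRUE) {
  if (nrow(g$nodes) < 1) gp_stop("empty graph")
  cd <- degree_centrality(g)
  cc <- harmonic_closeness(g)
  cb <- betweenness_centrality(g)
  sd_ <- if (rescale) minmax_rescale(cd) else cd
  sc <- if (rescale) minmax_rescale(cc) else cc
  sb <- if (rescale) minmax_rescale(cb) else cb
  data.frame(node = g$nodes$node, c_deg = unname(cd), c_clo = unname(cc),
             c_bet = unname(cb),
             combined = unname(weights$w_deg * sd_ + weights$w_clo * sc +
                                 weights$w_bet * sb))
}

#' Rank nodes by combined score
#'
#' Descending by combined score, ties broken by node symbol ascending;
#' 1-based ranks.
#'
#' @param scores data.frame from [combined_score()] or a named numeric
#'   vector.
#' @return the scores data.frame sorted, with a `rank` column added.
#' @export
rank_nodes <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores)))
    scores <- data.frame(node = names(scores), combined = unname(scores))
  ord <- order(-scores$combined, scores$node)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
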