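#' Markov Cluster Algorithm parameters
#'
#' @param inflation entrywise inflation exponent `r > 1` (default 3, the
#'   setting used for protein-association networks here).
#' @param expansion matrix-power expansion exponent `e >= 2` (default 2).
#' @param pruning entries below this are zeroed after each inflation
#'   (default 1e-5).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence when the largest entry change falls below this
#'   (default 1e-8).
#' @return list of parameters.
#' @export
mcl_params <- function(inflation = 3, expansion = 2, pruning = 1e-5,
                       max_iter = 200, tol = 1e-8) {
  if (inflation <= 1) gp_stop("inflation must be > 1")
  if (expansion < 2) gp_stop("expansion must be >= 2")
  list(inflation = inflation, expansion = expansion, pruning = pruning,
       max_iter = max_iter, tol = tol)
}

#' Markov clustering of a protein-association graph
#'
#' Runs MCL on the graph adjacency: self-loops of weight 1 are added, the
#' matrix is made column-stochastic, and expansion (matrix power) alternates
#' with inflation (entrywise power followed by column renormalization) and
#' pruning until the matrix stabilizes. Clusters are read from the attractor
#' rows of the limit matrix; attractors sharing nodes are merged. Cluster ids
#' are 1-based, numbered by each cluster's lexicographically first member.
#'
#' @param g a `ppa_graph`.
#' @param params a [mcl_params()] list.
#' @param use_weights use edge confidences as adjacency weights (default
#'   `TRUE`; `FALSE` uses binary adjacency).
#' @return list with `membership` (named integer vector) and `n_clusters`.
#' @export
mcl_cluster <- function(g, params = mcl_params(), use_weights = TRUE) {
  nodes <- g$nodes$node
  n <- length(nodes)
  if (n == 0) gp_stop("empty graph")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(g$edges)) {
    w <- if (use_weights) g$edges$confidence else rep(1, nrow(g$edges))
    A[cbind(g$edges$from, g$edges$to)] <- w
    A[cbind(g$edges$to, g$edges$from)] <- w
  }
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(params$max_iter)) {
    Mexp <- M
    for (k in seq_len(params$expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ params$inflation
    Minf[Minf < params$pruning] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < params$tol) break
    if (it == params$max_iter)
      gp_stop("MCL did not converge in ", params$max_iter,
              " iterations (residual ", format(delta), ")")
  }
  # attractors: nodes with positive mass on their own row
  attractors <- which(diag(M) > params$pruning)
  if (!length(attractors)) attractors <- seq_len(n)
  members <- lapply(attractors, function(i) which(M[i, ] > params$pruning))
  # merge attractor rows that overlap (overlapping attractor systems)
  clusters <- list()
  for (m in members) {
    hit <- which(vapply(clusters, function(cl) any(cl %in% m), TRUE))
    if (length(hit)) {
      merged <- sort(unique(c(unlist(clusters[hit]), m)))
      clusters <- clusters[-hit]
      clusters <- c(clusters, list(merged))
    } else clusters <- c(clusters, list(sort(m)))
  }
  assigned <- sort(unique(unlist(clusters)))
  orphan <- setdiff(seq_len(n), assigned)
  clusters <- c(clusters, lapply(orphan, identity))
  clusters <- clusters[order(vapply(clusters, function(cl) nodes[cl[1]], ""))]
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  names(membership) <- nodes
  list(membership = membership, n_clusters = length(clusters))
}
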