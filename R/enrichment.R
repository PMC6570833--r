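#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value `P(X >= k)` for a hypergeometric draw: `n`
#' genes sampled from a background of `N` of which `K` belong to the set.
#'
#' @param k observed overlap.
#' @param K set size within the background.
#' @param n query size within the background.
#' @param N background size.
#' @return upper-tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    gp_stop("inconsistent hypergeometric parameters")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation
#'
#' Per set, the overlap `k = |query int set int background|` is scored by the
#' hypergeometric upper tail; sets with no overlap are excluded. Results are
#' ranked by ascending p, ties by larger overlap then set_id, BH-adjusted
#' over all tested sets, and the first `top` are returned as seed pathways.
#'
#' @param query_genes character vector of query gene symbols.
#' @param db a `gene_set_db` (see [read_gmt()]).
#' @param background background gene universe; default the union of all DB
#'   genes.
#' @param top number of top sets returned (default 10); `Inf` returns all.
#' @return data.frame with columns `set_id`, `description`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `rank`.
#' @export
enrich_sets <- function(query_genes, db, background = NULL, top = 10) {
  if (is.null(background)) background <- unique(unlist(db))
  background <- unique(as.character(background))
  query <- intersect(unique(as.character(query_genes)), background)
  if (length(query) == 0)
    gp_stop("no query gene intersects the background")
  N <- length(background); n <- length(query)
  rows <- lapply(names(db), function(id) {
    members <- intersect(db[[id]], background)
    k <- length(intersect(query, members))
    if (k == 0) return(NULL)
    K <- length(members)
    data.frame(set_id = id,
               description = attr(db, "descriptions")[[id]] %||% "",
               k = k, K = K, n = n, N = N,
               p = hypergeom_tail(k, K, n, N))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) gp_stop("no gene set overlaps the query")
  rows$p_adj <- p.adjust(rows$p, method = "BH")
  rows <- rows[order(rows$p, -rows$k, rows$set_id), , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  head(rows, if (is.finite(top)) top else nrow(rows))
}

#' Pathway-pathway overlap scaffold
#'
#' Builds the reference pathway network used to connect seed pathways:
#' every DB set is a node, and two sets are linked iff the Jaccard index of
#' their member lists reaches `min_jaccard`, with the Jaccard index as the
#' edge weight.
#'
#' @param db a `gene_set_db`.
#' @param min_jaccard minimum Jaccard overlap for an edge (default 0.05).
#' @return a `pathway_network`: list with `nodes` (data.frame `pathway`,
#'   `role`) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
pathway_graph <- function(db, min_jaccard = 0.05) {
  ids <- names(db)
  edges <- list()
  if (length(ids) >= 2) {
    pairs <- combn(ids, 2)
    jac <- apply(pairs, 2, function(pr) {
      a <- db[[pr[1]]]; b <- db[[pr[2]]]
      length(intersect(a, b)) / length(union(a, b))
    })
    keep <- jac >= min_jaccard & jac > 0
    edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                        weight = jac[keep])
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  structure(list(nodes = data.frame(pathway = ids,
                                    role = rep("scaffold", length(ids))),
                 edges = edges),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  tab <- table(x$nodes$role)
  cat("pathway_network:", nrow(x$nodes), "pathways (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Complementary pathway network around seed pathways
#'
#' Starting from the scaffold subgraph induced on the seed pathways, the
#' seed components are greedily connected: at each step the shortest
#' scaffold path (fewest intermediate non-seed pathways; ties by larger
#' summed edge weight, then lexicographic path) joining two different
#' components is added, its intermediates becoming complementary nodes,
#' until one component remains or no connecting path exists (a warning is
#' then emitted).
#'
#' @param seeds character vector of seed pathway ids.
#' @param scaffold a `pathway_network` from [pathway_graph()].
#' @return a `pathway_network` whose nodes carry role `seed` or
#'   `complementary`; edges are the scaffold edges among included nodes.
#' @export
complementary_network <- function(seeds, scaffold) {
  seeds <- unique(as.character(seeds))
  absent <- setdiff(seeds, scaffold$nodes$pathway)
  if (length(absent))
    gp_stop("seed pathway absent from scaffold: ",
            paste(absent, collapse = ", "))
  ig <- igraph::graph_from_data_frame(
    scaffold$edges, directed = FALSE,
    vertices = scaffold$nodes$pathway)
  included <- seeds
  repeat {
    sub <- igraph::induced_subgraph(ig, included)
    comp <- igraph::components(sub)
    if (comp$no <= 1) break
    memb <- comp$membership[included]
    best <- NULL
    for (ci in seq_len(comp$no - 1)) for (cj in (ci + 1):comp$no) {
      from_set <- included[memb == ci]; to_set <- included[memb == cj]
      # intermediates may be any scaffold pathway, not only seeds
      for (f in from_set) {
        sp <- suppressWarnings(igraph::all_shortest_paths(
          ig, from = f, to = to_set, weights = NA)$vpaths)
        for (path in sp) {
          pn <- igraph::as_ids(path)
          if (length(pn) < 2) next
          inter <- setdiff(pn[-c(1, length(pn))], included)
          w <- path_weight(ig, pn)
          cand <- list(n_inter = length(inter), weight = w,
                       key = paste(pn, collapse = "|"), inter = inter)
          if (is.null(best) || better_path(cand, best)) best <- cand
        }
      }
    }
    if (is.null(best)) {
      warning("seed components cannot all be connected through the scaffold",
              call. = FALSE)
      break
    }
    included <- c(included, best$inter)
  }
  # prune complementary nodes made redundant by later additions: every
  # retained one must be a cut node of the final network
  n_comp <- function(nodeset) {
    igraph::components(igraph::induced_subgraph(ig, nodeset))$no
  }
  repeat {
    extras <- sort(setdiff(included, seeds))
    drop <- NULL
    for (v in extras) {
      if (n_comp(setdiff(included, v)) <= n_comp(included)) { drop <- v; break }
    }
    if (is.null(drop)) break
    included <- setdiff(included, drop)
  }
  nodes <- data.frame(pathway = included,
                      role = ifelse(included %in% seeds, "seed",
                                    "complementary"))
  keep <- scaffold$edges$from %in% included & scaffold$edges$to %in% included
  structure(list(nodes = nodes,
                 edges = scaffold$edges[keep, , drop = FALSE]),
            class = "pathway_network")
}

path_weight <- function(ig, pn) {
  if (length(pn) < 2) return(0)
  sum(vapply(seq_len(length(pn) - 1), function(i) {
    e <- igraph::get_edge_ids(ig, c(pn[i], pn[i + 1]))
    igraph::E(ig)$weight[e]
  }, 0))
}

better_path <- function(a, b) {
  if (a$n_inter != b$n_inter) return(a$n_inter < b$n_inter)
  if (abs(a$weight - b$weight) > 1e-12) return(a$weight > b$weight)
  a$key < b$key
}
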