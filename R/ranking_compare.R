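#' Pathway ranking by mean member-protein combined score
#'
#' For every gene set with at least one member among the analyzed network's
#' nodes, the pathway score is the arithmetic mean of the combined centrality
#' scores of its contributing proteins; pathways with no member present are
#' omitted. Ranked descending, ties broken by set_id.
#'
#' @param db a `gene_set_db`.
#' @param scores named numeric vector of combined node scores, or the
#'   data.frame from [combined_score()].
#' @return data.frame with columns `set_id`, `n_contributing`,
#'   `mean_combined`, `rank`.
#' @export
pathway_rank <- function(db, scores) {
  if (is.data.frame(scores))
    scores <- setNames(scores$combined, scores$node)
  rows <- lapply(names(db), function(id) {
    members <- intersect(db[[id]], names(scores))
    if (length(members) == 0) return(NULL)
    data.frame(set_id = id, n_contributing = length(members),
               mean_combined = mean(scores[members]))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(set_id = character(), n_contributing = integer(),
                      mean_combined = numeric(), rank = integer()))
  rows <- rows[order(-rows$mean_combined, rows$set_id), , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

#' Venn regions of 2-4 named sets
#'
#' Every nonempty-membership region of the Venn diagram with its exact
#' member set. Regions are named by the `+`-joined list names of the lists
#' the region belongs to.
#'
#' @param named_lists named list of 2-4 character vectors.
#' @return named list of character vectors, one per region (including empty
#'   regions), with a `counts` attribute.
#' @export
venn_regions <- function(named_lists) {
  k <- length(named_lists)
  if (k < 2 || k > 4) gp_stop("venn_regions needs 2-4 named lists")
  if (is.null(names(named_lists)) || any(!nzchar(names(named_lists))))
    gp_stop("every list needs a name")
  sets <- lapply(named_lists, function(v) unique(as.character(v)))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  regions <- list()
  for (mask in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    name <- paste(names(sets)[inset], collapse = "+")
    inregion <- apply(membership, 1, function(m) identical(unname(m), inset))
    regions[[name]] <- universe[inregion]
  }
  stopifnot(sum(lengths(regions)) == length(universe))
  attr(regions, "counts") <- lengths(regions)
  regions
}

#' Partition two pathway lists into common and method-exclusive sets
#'
#' Consensus merge of two analysis methods: the intersection and each
#' method's exclusive pathways, an exact partition of the union.
#'
#' @param pathways_m1,pathways_m2 character vectors of pathway ids.
#' @return list with `common`, `only_m1`, `only_m2`.
#' @export
merge_methods <- function(pathways_m1, pathways_m2) {
  m1 <- unique(as.character(pathways_m1))
  m2 <- unique(as.character(pathways_m2))
  list(common = sort(intersect(m1, m2)),
       only_m1 = sort(setdiff(m1, m2)),
       only_m2 = sort(setdiff(m2, m1)))
}

#' Disease-disease network from shared pathway profiles
#'
#' Nodes are diseases; two diseases are linked iff they share at least
#' `min_shared` pathways, weighted by the Jaccard index of their pathway
#' sets. Diseases with no edge are retained and flagged as isolated.
#'
#' @param profiles named list mapping disease label to its set of pathway
#'   ids (its molecular background).
#' @param min_shared minimum number of shared pathways for an edge
#'   (default 1).
#' @return list with `nodes` (data.frame `disease`, `isolated`) and `edges`
#'   (data.frame `from`, `to`, `n_shared`, `weight`).
#' @export
disease_network <- function(profiles, min_shared = 1) {
  if (length(profiles) < 2) gp_stop("need at least 2 disease profiles")
  if (any(lengths(profiles) == 0)) gp_stop("empty disease profile")
  profiles <- lapply(profiles, function(v) unique(as.character(v)))
  labs <- names(profiles)
  pairs <- combn(labs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- profiles[[pairs[1, i]]]; b <- profiles[[pairs[2, i]]]
    shared <- length(intersect(a, b))
    if (shared < min_shared) return(NULL)
    data.frame(from = pairs[1, i], to = pairs[2, i], n_shared = shared,
               weight = shared / length(union(a, b)))
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        n_shared = integer(), weight = numeric())
  nodes <- data.frame(disease = labs,
                      isolated = !(labs %in% c(edges$from, edges$to)))
  list(nodes = nodes, edges = edges)
}
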