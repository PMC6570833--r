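#' Map gene symbols to canonical protein symbols
#'
#' Resolves each gene through an alias table (many-to-one allowed) and
#' deduplicates the canonical targets. Genes absent from the table are
#' reported with a warning, never silently dropped; by default an unmapped
#' gene maps to itself.
#'
#' @param genes character vector of gene symbols.
#' @param alias_table named character vector (`gene -> protein`) or
#'   data.frame with columns `gene`, `protein`. `NULL` means identity.
#' @param identity_fallback keep unmapped genes under their own symbol
#'   (default `TRUE`); if `FALSE` they are excluded (still warned about).
#' @return character vector of distinct canonical protein symbols, with an
#'   `unmapped` attribute listing genes absent from the alias table.
#' @export
map_genes_to_proteins <- function(genes, alias_table = NULL,
                                  identity_fallback = TRUE) {
  genes <- unique(as.character(genes))
  if (is.data.frame(alias_table))
    alias_table <- setNames(as.character(alias_table$protein),
                            alias_table$gene)
  mapped <- if (is.null(alias_table)) genes else
    unname(alias_table[genes])
  unmapped <- genes[is.na(mapped)]
  if (length(unmapped))
    warning(length(unmapped), " gene(s) not in alias table: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  if (identity_fallback) mapped[is.na(mapped)] <- unmapped
  out <- unique(mapped[!is.na(mapped)])
  if (length(out) == 0) gp_stop("no genes could be mapped to proteins")
  attr(out, "unmapped") <- unmapped
  out
}

#' Shell caps for seed-network enrichment
#'
#' @param max_shell1 maximum first-shell interactors (default 20).
#' @param max_shell2 maximum second-shell interactors (default 10).
#' @return list with `max_shell1`, `max_shell2`, `max_total`.
#' @export
shell_caps <- function(max_shell1 = 20, max_shell2 = 10) {
  if (max_shell1 < 0 || max_shell2 < 0) gp_stop("shell caps must be >= 0")
  list(max_shell1 = max_shell1, max_shell2 = max_shell2,
       max_total = max_shell1 + max_shell2)
}

#' Expand a seed protein set into an enriched association network
#'
#' Builds the protein-association network around a seed set from a
#' thresholded interaction table, adding at most `caps$max_shell1`
#' first-shell interactors (non-seed proteins adjacent to at least one seed,
#' ranked by the sum of confidences of their edges to seeds, ties broken by
#' symbol) and then at most `caps$max_shell2` second-shell interactors
#' (proteins adjacent to at least one first-shell node, ranked by summed
#' confidence to the current network). All qualifying edges among included
#' nodes are materialized and nodes left without any edge are removed.
#'
#' @param interactions an `interaction_table` (see [read_interactions()]).
#' @param seeds character vector of seed protein symbols.
#' @param caps a [shell_caps()] list.
#' @param min_score minimum edge confidence retained (default 0.400).
#' @return a `ppa_graph` with node roles `seed`, `shell1`, `shell2`.
#' @export
expand_seed_network <- function(interactions, seeds, caps = shell_caps(),
                                min_score = 0.400) {
  seeds <- unique(as.character(seeds))
  tab <- interactions[interactions$combined_score >= min_score, , drop = FALSE]
  present <- unique(c(tab$protein_a, tab$protein_b))
  absent <- setdiff(seeds, present)
  if (length(absent) == length(seeds))
    gp_stop("no seed present in the interaction table; missing: ",
            paste(absent, collapse = ", "))
  sum_conf_to <- function(nodeset) {
    # summed confidence from each outside protein to `nodeset`
    in_a <- tab$protein_a %in% nodeset
    in_b <- tab$protein_b %in% nodeset
    ends <- c(tab$protein_b[in_a & !in_b], tab$protein_a[in_b & !in_a])
    conf <- c(tab$combined_score[in_a & !in_b], tab$combined_score[in_b & !in_a])
    if (!length(ends)) return(numeric())
    vapply(split(conf, ends), sum, 0)
  }
  pick_top <- function(scores, k) {
    if (!length(scores) || k <= 0) return(character())
    ord <- order(-scores, names(scores))
    names(scores)[ord][seq_len(min(k, length(scores)))]
  }
  shell1 <- pick_top(sum_conf_to(seeds), caps$max_shell1)
  scores2 <- sum_conf_to(c(seeds, shell1))
  # second-shell candidates must touch a shell-1 node
  touch1 <- unique(c(tab$protein_b[tab$protein_a %in% shell1],
                     tab$protein_a[tab$protein_b %in% shell1]))
  scores2 <- scores2[names(scores2) %in% touch1]
  shell2 <- pick_top(scores2, caps$max_shell2)
  nodes <- data.frame(
    node = c(seeds, shell1, shell2),
    role = rep(c("seed", "shell1", "shell2"),
               c(length(seeds), length(shell1), length(shell2))))
  keep <- tab$protein_a %in% nodes$node & tab$protein_b %in% nodes$node
  edges <- data.frame(from = tab$protein_a[keep], to = tab$protein_b[keep],
                      confidence = tab$combined_score[keep])
  connected <- unique(c(edges$from, edges$to))
  nodes <- nodes[nodes$node %in% connected, , drop = FALSE]
  ppa_graph(nodes, edges)
}
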