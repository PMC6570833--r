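# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths (and igraph) so they
# can serve as cross-checks.

# --- graph fixtures ---------------------------------------------------------

edges_df <- function(from, to, confidence = 0.9) {
  data.frame(from = as.character(from), to = as.character(to),
             confidence = rep_len(confidence, length(from)))
}

graph_fixture <- function(nodes, from, to, confidence = 0.9) {
  ppa_graph(data.frame(node = nodes, role = "seed"),
            edges_df(from, to, confidence))
}

# two K4 cliques joined by one bridge edge a1-b1
bridged_k4s <- function() {
  ea <- t(combn(paste0("a", 1:4), 2))
  eb <- t(combn(paste0("b", 1:4), 2))
  e <- rbind(ea, eb, c("a1", "b1"))
  graph_fixture(c(paste0("a", 1:4), paste0("b", 1:4)), e[, 1], e[, 2])
}

random_graph <- function(n, p = 0.4) {
  nodes <- paste0("n", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  graph_fixture(nodes, pairs[keep, 1], pairs[keep, 2])
}

# --- brute-force centralities (simple-path enumeration, no BFS library) -----

adj_list <- function(g) {
  nodes <- g$nodes$node
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(g$edges))) {
    f <- g$edges$from[i]; t <- g$edges$to[i]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  adj
}

# all simple paths from s to t as list of node vectors
simple_paths <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (nb in adj[[last]]) if (!nb %in% path) walk(c(path, nb))
  }
  walk(s)
  out
}

# degree / harmonic closeness / betweenness by exhaustive path enumeration,
# normalized as the package documents
brute_centralities <- function(g) {
  nodes <- g$nodes$node
  n <- length(nodes)
  adj <- adj_list(g)
  deg <- vapply(nodes, function(v) length(adj[[v]]), 0) / max(n - 1, 1)
  clo <- setNames(numeric(n), nodes)
  bet <- setNames(numeric(n), nodes)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- nodes[i]; t <- nodes[j]
      paths <- simple_paths(adj, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, 0L) - 1L
      d <- min(lens)
      geo <- paths[lens == d]
      clo[s] <- clo[s] + 1 / d
      clo[t] <- clo[t] + 1 / d
      for (v in setdiff(nodes, c(s, t))) {
        through <- sum(vapply(geo, function(p) v %in% p, TRUE))
        bet[v] <- bet[v] + through / length(geo)
      }
    }
    clo <- clo / (n - 1)
    if (n > 2) bet <- bet / ((n - 1) * (n - 2) / 2)
  }
  list(deg = deg, clo = clo, bet = bet)
}

# --- HWE exact enumeration over genotype configurations ---------------------

# two-sided exact HWE p by enumerating every genotype triple with the same
# n and allele-1 total, scoring each by its multinomial x HWE-conditional
# probability computed directly from factorials
brute_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n1 <- 2 * n_hom1 + n_het
  configs <- list(); probs <- numeric()
  for (h1 in 0:n) for (h in 0:(n - h1)) {
    h2 <- n - h1 - h
    if (2 * h1 + h != n1) next
    configs[[length(configs) + 1]] <- c(h1, h, h2)
    probs <- c(probs, factorial(n) * 2^h /
                 (factorial(h1) * factorial(h) * factorial(h2)))
  }
  probs <- probs / sum(probs)
  obs <- which(vapply(configs, function(cf)
    all(cf == c(n_hom1, n_het, n_hom2)), TRUE))
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}

# --- misc -------------------------------------------------------------------

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# synthetic end-to-end pipeline inputs written into a fresh directory
pipeline_fixture <- function(dir = tempfile("pipe"), seed = 11) {
  dir.create(dir)
  spec <- snp_sim_spec(sprintf("rs%03d", 1:12), f_u = 0.3,
                       target_or = c(rep(2.2, 4), rep(0.45, 2), rep(1, 6)),
                       missing_rate = 0.01)
  gm_cd <- simulate_genotypes(300, 300, spec, seed = seed,
                              case_label = "CD", control_label = "HC")
  gm_uc <- simulate_genotypes(200, 300, spec, seed = seed + 1,
                              case_label = "UC", control_label = "HC")
  uc_calls <- gm_uc$calls[gm_uc$groups == "UC", , drop = FALSE]
  rownames(uc_calls) <- paste0("uc_", seq_len(nrow(uc_calls)))
  gm <- genotype_matrix(
    rbind(gm_cd$calls[gm_cd$groups == "CD", , drop = FALSE],
          uc_calls,
          gm_cd$calls[gm_cd$groups == "HC", , drop = FALSE]),
    c(rep("CD", 300), rep("UC", 200), rep("HC", 300)),
    gm_cd$snps)
  # risk loci carry the genes that seed the networks
  gm$snps$locus <- c("TLR4", "NOD2", "STAT3", "IL6", "STX8", "NFATC2",
                     paste0("NULL", 1:6))
  geno_path <- file.path(dir, "genotypes.tsv")
  write_genotypes(gm, geno_path)
  annot_path <- file.path(dir, "annotation.tsv")
  write.table(gm$snps, annot_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ppa <- simulate_ppa(network_sim_spec(module_sizes = c(8, 8, 8)),
                      seed = seed)
  # alias the risk genes onto simulated proteins so expansion finds seeds
  prot <- unique(c(ppa$protein_a, ppa$protein_b))
  ppa_path <- file.path(dir, "interactions.tsv")
  extra <- data.frame(protein_a = c("TLR4", "NOD2", "STAT3", "IL6",
                                    "STX8", "NFATC2"),
                      protein_b = prot[1:6],
                      combined_score = 0.9)
  write_interactions(interaction_table(
    rbind(as.data.frame(ppa)[c("protein_a", "protein_b", "combined_score")],
          extra)), ppa_path)
  genes <- c("TLR4", "NOD2", "STAT3", "IL6", "STX8", "NFATC2", prot[1:10])
  sets <- list(PW_A = genes[1:6], PW_B = genes[c(1:3, 7:10)],
               PW_C = genes[c(4:6, 11:14)], PW_D = prot[5:12],
               PW_E = c(genes[1:2], prot[10:16]))
  gmt_path <- file.path(dir, "sets.gmt")
  write_gmt(gene_set_db(sets), gmt_path)
  list(dir = dir, genotypes = geno_path, annotation = annot_path,
       interactions = ppa_path, gmt = gmt_path)
}
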