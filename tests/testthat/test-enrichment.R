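test_that("hypergeometric tail matches closed forms and enumeration", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)
  expect_equal(hypergeom_tail(2, 2, 2, 4), 1 / 6)
  expect_error(hypergeom_tail(3, 2, 2, 4), "inconsistent")
  # enumeration of the mass function
  enum_tail <- function(k, K, n, N) {
    ks <- k:min(K, n)
    sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
  }
  set.seed(17)
  for (rep in 1:60) {
    N <- sample(5:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N), enum_tail(k, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("over-representation ranks planted sets first and caps at top", {
  # query identical to one set, disjoint others
  db <- gene_set_db(list(HIT = paste0("q", 1:6),
                         OTHER1 = paste0("x", 1:8),
                         OTHER2 = paste0("y", 1:8)))
  res <- enrich_sets(paste0("q", 1:6), db)
  expect_equal(res$set_id[1], "HIT")
  expect_equal(res$k[1], 6)
  # planted synthetic DB
  db2 <- simulate_genesets(30, c(10, 30), query = paste0("G", 1:10), k = 8,
                           seed = 18)
  res2 <- enrich_sets(paste0("G", 1:10), db2)
  expect_equal(res2$set_id[1], "PLANTED")
  # top cap
  many <- setNames(lapply(1:15, function(i) c("q1", paste0("f", i, 1:5))),
                   paste0("S", 1:15))
  res3 <- enrich_sets(c("q1", "q2"), gene_set_db(many),
                      background = c("q1", "q2", unlist(many)), top = 10)
  expect_equal(nrow(res3), 10)
  # k = 0 planted set is excluded
  db4 <- simulate_genesets(10, c(5, 10), query = paste0("G", 1:10), k = 0,
                           seed = 19)
  res4 <- tryCatch(enrich_sets(paste0("G", 1:10), db4),
                   gwaspathnet_error = function(e) NULL)
  expect_true(is.null(res4) || !"PLANTED" %in% res4$set_id)
  expect_error(enrich_sets("absent_gene", db), "background")
})

test_that("enrichment ranking ignores DB file order except via tie-breaks", {
  db <- simulate_genesets(20, c(8, 20), query = paste0("G", 1:10), k = 6,
                          seed = 20)
  sets <- unclass(db)
  attributes(sets) <- list(names = names(db))
  perm <- rev(seq_along(sets))
  db_perm <- gene_set_db(sets[perm])
  r1 <- enrich_sets(paste0("G", 1:10), db, top = Inf)
  r2 <- enrich_sets(paste0("G", 1:10), db_perm, top = Inf)
  expect_equal(r1$set_id, r2$set_id)
  expect_equal(r1$p, r2$p)
})

test_that("pathway scaffold equals brute-force pairwise Jaccard", {
  dup <- gene_set_db(list(A = c("g1", "g2"), B = c("g1", "g2"),
                          C = c("z1", "z2")))
  sc <- pathway_graph(dup, min_jaccard = 0.05)
  expect_equal(nrow(sc$edges), 1)
  expect_equal(sc$edges$weight, 1)
  set.seed(21)
  db <- simulate_genesets(12, c(5, 15), query = paste0("G", 1:8), k = 4,
                          seed = 21)
  sc2 <- pathway_graph(db, min_jaccard = 0.01)
  for (i in seq_len(nrow(sc2$edges))) {
    a <- db[[sc2$edges$from[i]]]; b <- db[[sc2$edges$to[i]]]
    expect_equal(sc2$edges$weight[i],
                 length(intersect(a, b)) / length(union(a, b)))
  }
  # completeness: every qualifying pair is present
  ids <- names(db)
  pairs <- combn(ids, 2)
  jac <- apply(pairs, 2, function(pr)
    length(intersect(db[[pr[1]]], db[[pr[2]]])) /
      length(union(db[[pr[1]]], db[[pr[2]]])))
  expect_equal(nrow(sc2$edges), sum(jac >= 0.01))
})

test_that("complementary network connects seed components minimally", {
  db <- gene_set_db(list(
    S1 = paste0("a", 1:10),
    S2 = c(paste0("a", 1:5), paste0("b", 1:5)),
    MID = c(paste0("b", 1:5), paste0("c", 1:5)),
    S3 = c(paste0("c", 1:5), paste0("d", 1:5)),
    FAR = paste0("z", 1:10)))
  sc <- pathway_graph(db, min_jaccard = 0.05)
  # seeds S1+S2 and S3 connect only through MID
  net <- complementary_network(c("S1", "S2", "S3"), sc)
  roles <- setNames(net$nodes$role, net$nodes$pathway)
  expect_equal(unname(roles["MID"]), "complementary")
  expect_setequal(net$nodes$pathway, c("S1", "S2", "S3", "MID"))
  # already-connected seeds need no complementary nodes
  net2 <- complementary_network(c("S1", "S2"), sc)
  expect_true(all(net2$nodes$role == "seed"))
  # unreachable seed components leave the graph split, with a warning
  expect_warning(net3 <- complementary_network(c("S1", "FAR"), sc),
                 "cannot")
  expect_setequal(net3$nodes$pathway, c("S1", "FAR"))
  expect_error(complementary_network("NOPE", sc), "absent")
})

test_that("removing any added complementary pathway disconnects the seeds", {
  set.seed(22)
  for (rep in 1:5) {
    db <- simulate_genesets(15, c(5, 20), query = paste0("G", 1:8), k = 4,
                            seed = 300 + rep)
    sc <- pathway_graph(db, min_jaccard = 0.01)
    if (nrow(sc$edges) == 0) next
    seeds <- sample(names(db), 4)
    net <- suppressWarnings(complementary_network(seeds, sc))
    added <- net$nodes$pathway[net$nodes$role == "complementary"]
    full_ig <- igraph::graph_from_data_frame(
      net$edges[c("from", "to")], directed = FALSE,
      vertices = net$nodes$pathway)
    n_comp <- igraph::components(full_ig)$no
    for (drop in added) {
      sub <- igraph::induced_subgraph(
        full_ig, setdiff(net$nodes$pathway, drop))
      expect_gt(igraph::components(sub)$no, n_comp)
    }
  }
})
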