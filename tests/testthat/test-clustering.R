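two_triangles <- function() {
  graph_fixture(c("a1", "a2", "a3", "b1", "b2", "b3"),
                c("a1", "a2", "a3", "b1", "b2", "b3"),
                c("a2", "a3", "a1", "b2", "b3", "b1"))
}

test_that("MCL separates disjoint triangles and splits bridged cliques", {
  cl <- mcl_cluster(two_triangles())
  expect_equal(cl$n_clusters, 2)
  m <- cl$membership
  expect_length(unique(m[c("a1", "a2", "a3")]), 1)
  expect_length(unique(m[c("b1", "b2", "b3")]), 1)
  expect_true(m["a1"] != m["b1"])

  cl2 <- mcl_cluster(bridged_k4s())
  expect_equal(cl2$n_clusters, 2)
  m2 <- cl2$membership
  expect_length(unique(m2[paste0("a", 1:4)]), 1)
  expect_length(unique(m2[paste0("b", 1:4)]), 1)

  solo <- ppa_graph("only")
  expect_equal(mcl_cluster(solo)$n_clusters, 1)
})

test_that("MCL clusters never span components; count non-decreasing in r", {
  set.seed(15)
  for (rep in 1:5) {
    tab <- simulate_ppa(network_sim_spec(module_sizes = c(8, 8, 8),
                                         p_out = 0), seed = rep)
    mod <- attr(tab, "module")
    g <- ppa_graph(data.frame(node = names(mod), role = "seed"),
                   edges_df(tab$protein_a, tab$protein_b,
                            tab$combined_score))
    comp <- igraph::components(as_igraph(g))$membership
    cl <- mcl_cluster(g)
    # cluster must be constant-component
    split_comp <- split(comp[names(cl$membership)], cl$membership)
    expect_true(all(vapply(split_comp,
                           function(v) length(unique(v)) == 1, TRUE)))
  }
  # inflation sweep on a planted-partition fixture
  tab <- simulate_ppa(network_sim_spec(), seed = 99)
  mod <- attr(tab, "module")
  g <- ppa_graph(data.frame(node = names(mod), role = "seed"),
                 edges_df(tab$protein_a, tab$protein_b, tab$combined_score))
  counts <- vapply(c(1.5, 2, 3, 5), function(r) {
    mcl_cluster(g, mcl_params(inflation = r))$n_clusters
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("MCL at inflation 3 recovers planted four-module partitions", {
  aris <- vapply(1:10, function(s) {
    tab <- simulate_ppa(network_sim_spec(module_sizes = rep(10, 4),
                                         p_in = 0.8, p_out = 0.02),
                        seed = 100 + s)
    mod <- attr(tab, "module")
    g <- ppa_graph(data.frame(node = names(mod), role = "seed"),
                   edges_df(tab$protein_a, tab$protein_b,
                            tab$combined_score))
    cl <- mcl_cluster(g, mcl_params(inflation = 3))
    adjusted_rand(cl$membership[names(mod)], mod)
  }, 0)
  expect_gt(mean(aris), 0.9)
})

test_that("edge-betweenness communities split at bridges and handle edge cases", {
  gn <- edge_betweenness_communities(bridged_k4s())
  expect_equal(gn$n_clusters, 2)
  expect_length(unique(gn$membership[paste0("a", 1:4)]), 1)
  expect_length(unique(gn$membership[paste0("b", 1:4)]), 1)
  # returned partition beats the trivial single cluster
  expect_gte(gn$modularity, 0)

  empty <- ppa_graph(paste0("x", 1:5))
  gn2 <- edge_betweenness_communities(empty)
  expect_equal(gn2$n_clusters, 5)

  # communities never span disconnected components
  g <- two_triangles()
  gn3 <- edge_betweenness_communities(g)
  expect_true(gn3$membership["a1"] != gn3$membership["b1"])
})

test_that("edge-betweenness communities agree with the igraph reference", {
  set.seed(16)
  for (rep in 1:5) {
    tab <- simulate_ppa(network_sim_spec(module_sizes = c(8, 8),
                                         p_in = 0.9, p_out = 0.05),
                        seed = 200 + rep)
    mod <- attr(tab, "module")
    g <- ppa_graph(data.frame(node = names(mod), role = "seed"),
                   edges_df(tab$protein_a, tab$protein_b,
                            tab$combined_score))
    ours <- edge_betweenness_communities(g)
    ref <- igraph::cluster_edge_betweenness(as_igraph(g), weights = NA)
    expect_gte(ours$modularity,
               igraph::modularity(as_igraph(g), igraph::membership(ref)) -
                 1e-9)
    expect_equal(adjusted_rand(ours$membership[names(mod)], mod),
                 adjusted_rand(igraph::membership(ref)[names(mod)], mod),
                 tolerance = 0.2)
  }
})
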