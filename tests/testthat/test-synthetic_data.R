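test_that("case frequency inverts the allelic odds ratio", {
  expect_equal(case_frequency(0.3, 1.0), 0.3)
  expect_equal(case_frequency(0.3, 2.0), 0.6 / 1.3)
  # plugging f_A back into the OR definition returns the target
  set.seed(26)
  for (rep in 1:20) {
    f_u <- runif(1, 0.05, 0.95)
    or_ <- exp(runif(1, -1.5, 1.5))
    f_a <- case_frequency(f_u, or_)
    expect_equal((f_a / (1 - f_a)) / (f_u / (1 - f_u)), or_,
                 tolerance = 1e-12)
  }
  # the published IBD rs10761659 frequency pair
  expect_equal(case_frequency(0.495, 0.7212), 0.414, tolerance = 0.001)
  expect_error(case_frequency(0, 2), "f_u")
})

test_that("genotype simulation is seed-pure and matches its targets", {
  spec <- snp_sim_spec(c("rs1", "rs2"), f_u = c(0.2, 0.4),
                       target_or = c(1, 1.5), missing_rate = 0.05)
  g1 <- simulate_genotypes(50, 50, spec, seed = 27)
  g2 <- simulate_genotypes(50, 50, spec, seed = 27)
  expect_identical(g1$calls, g2$calls)
  expect_false(identical(g1$calls,
                         simulate_genotypes(50, 50, spec, seed = 28)$calls))
  # control frequency converges to f_U
  big <- simulate_genotypes(100, 10000,
                            snp_sim_spec("rs1", 0.35, 2), seed = 29)
  ctrl <- big$calls[big$groups == "HC", 1]
  expect_lt(abs(mean(ctrl, na.rm = TRUE) / 2 - 0.35), 0.01)
  expect_error(simulate_genotypes(0, 10, spec, seed = 1), "positive")
})

test_that("estimated odds ratios are nearly unbiased at large n", {
  # moderate replicate count; the acceptance suite runs the full design
  for (or_true in c(0.5, 2)) {
    ors <- vapply(1:40, function(s) {
      gm <- simulate_genotypes(2000, 2000,
                               snp_sim_spec("rs1", 0.3, or_true),
                               seed = 1000 + s)
      t <- count_alleles(gm, "rs1", "CASE", "HC")
      odds_ratio(t)$or_
    }, 0)
    expect_lt(abs(mean(ors) / or_true - 1), 0.05)
  }
})

test_that("simulated interaction networks respect their planted structure", {
  spec <- network_sim_spec(module_sizes = c(6, 6, 6), p_out = 0)
  tab <- simulate_ppa(spec, seed = 30)
  expect_identical(as.data.frame(tab),
                   as.data.frame(simulate_ppa(spec, seed = 30)))
  mod <- attr(tab, "module")
  g <- igraph::graph_from_data_frame(
    tab[c("protein_a", "protein_b")], directed = FALSE,
    vertices = names(mod))
  # p_out = 0: thresholded graph splits into one component per module
  # (plus possible isolated vertices at p_in < 1)
  comp <- igraph::components(g)$membership
  for (m in unique(mod)) {
    members <- names(mod)[mod == m]
    linked <- members[igraph::degree(g, members) > 0]
    if (length(linked)) expect_length(unique(comp[linked]), 1)
  }
  # confidences straddle 0.400 as configured
  spec2 <- network_sim_spec(module_sizes = c(10, 10), p_in = 0.8,
                            p_out = 0.5, conf_out_below = 1)
  tab2 <- simulate_ppa(spec2, seed = 31)
  mod2 <- attr(tab2, "module")
  between <- mod2[tab2$protein_a] != mod2[tab2$protein_b]
  expect_true(all(tab2$combined_score[between] < 0.4))
  expect_true(all(tab2$combined_score[!between] > 0.4))
})

test_that("gene-set simulation plants exactly the requested overlap", {
  query <- paste0("G", 1:10)
  db <- simulate_genesets(25, c(8, 20), query = query, k = 8, seed = 32)
  expect_identical(names(db),
                   names(simulate_genesets(25, c(8, 20), query = query,
                                           k = 8, seed = 32)))
  expect_length(intersect(db$PLANTED, query), 8)
  others <- setdiff(names(db), "PLANTED")
  shared <- vapply(others, function(id)
    length(intersect(db[[id]], query)), 0L)
  expect_true(all(shared <= 1))
  expect_error(simulate_genesets(5, c(5, 8), query = "g", k = 3, seed = 1),
               "exceeds")
})
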