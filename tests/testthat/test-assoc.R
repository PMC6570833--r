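make_gm <- function(aff, unaff, snp = "rs1") {
  calls <- matrix(c(aff, unaff), ncol = 1,
                  dimnames = list(paste0("s", seq_len(length(aff) +
                                                        length(unaff))),
                                  snp))
  genotype_matrix(calls, rep(c("CASE", "HC"), c(length(aff), length(unaff))))
}

test_that("allele counting matches direct tallies and excludes missing", {
  t <- count_alleles(make_gm(c(2, 1, 0), c(0, 0)), "rs1", "CASE", "HC")
  expect_equal(t, c(a = 3L, b = 3L, c = 0L, d = 4L))
  t2 <- count_alleles(make_gm(c(1, NA), 1), "rs1", "CASE", "HC")
  expect_equal(t2, c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_error(count_alleles(make_gm(c(NA, NA), 1), "rs1", "CASE", "HC"),
               "zero called")
  expect_error(count_alleles(make_gm(1, 1), "rs1", "CASE", "XX"),
               "group label")
  # enumeration oracle on random matrices
  set.seed(1)
  for (rep in 1:20) {
    aff <- sample(c(0:2, NA), 15, replace = TRUE)
    un <- sample(c(0:2, NA), 12, replace = TRUE)
    if (all(is.na(aff)) || all(is.na(un))) next
    t <- count_alleles(make_gm(aff, un), "rs1", "CASE", "HC")
    a <- sum(aff[!is.na(aff)])
    expect_equal(unname(t["a"]), a)
    expect_equal(unname(t["b"]), 2 * sum(!is.na(aff)) - a)
    expect_equal(unname(t["c"]), sum(un[!is.na(un)]))
  }
})

test_that("allelic chi-square equals the cell-by-cell Pearson statistic", {
  expect_equal(allelic_chi2(c(10, 10, 10, 10))$chi2, 0)
  expect_equal(allelic_chi2(c(20, 0, 0, 20))$chi2, 40)
  expect_error(allelic_chi2(c(0, 0, 5, 5)), "zero margin")
  # independent observed-vs-expected formulation
  pearson <- function(t) {
    m <- matrix(t, 2, byrow = TRUE)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(2)
  for (rep in 1:50) {
    t <- sample(1:100, 4, replace = TRUE)
    expect_equal(allelic_chi2(t)$chi2, pearson(t), tolerance = 1e-12)
  }
  expect_equal(allelic_chi2(c(30, 70, 10, 90))$chi2,
               pearson(c(30, 70, 10, 90)))
})

test_that("chi-square survival matches the df=1 closed form and is monotone", {
  x <- c(0, 0.5, 1, 2, 5, 10, 20)
  expect_equal(chi2_sf(x, 1), 2 * (1 - pnorm(sqrt(x))), tolerance = 1e-10)
  expect_equal(chi2_sf(0, 1), 1)
  p <- chi2_sf(seq(0, 30, by = 0.5), 1)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(chi2_sf(-1, 1), "non-negative")
})

test_that("odds ratio matches the cross product, with CI and conventions", {
  or1 <- odds_ratio(c(42, 58, 42, 58))
  expect_equal(or1$or_, 1)
  or2 <- odds_ratio(c(10, 90, 5, 95))
  expect_equal(or2$or_, (10 * 95) / (90 * 5))
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)
  expect_equal(or2$ci_low, exp(log(or2$or_) - qnorm(0.975) * se))
  # scale invariance
  expect_equal(odds_ratio(c(3, 7, 4, 6))$or_,
               odds_ratio(10 * c(3, 7, 4, 6))$or_)
  # zero-cell conventions: literal quotient, CI undefined
  z <- odds_ratio(c(0, 10, 5, 5))
  expect_equal(z$or_, 0)
  expect_true(is.na(z$ci_low))
  expect_equal(odds_ratio(c(5, 0, 5, 5))$or_, Inf)
  h <- odds_ratio(c(0, 10, 5, 5), haldane = TRUE)
  expect_equal(h$or_, (0.5 * 5.5) / (10.5 * 5.5))
  expect_false(is.na(h$ci_low))
})

test_that("HWE exact test equals full enumeration", {
  expect_equal(hwe_exact(10, 0, 0), 1)
  expect_equal(hwe_exact(0, 4, 0), brute_hwe(0, 4, 0))
  expect_error(hwe_exact(0, 0, 0), "zero")
  set.seed(3)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    parts <- sort(sample(0:n, 2, replace = TRUE))
    cf <- c(parts[1], parts[2] - parts[1], n - parts[2])
    expect_equal(hwe_exact(cf[1], cf[2], cf[3]),
                 brute_hwe(cf[1], cf[2], cf[3]),
                 tolerance = 1e-10)
  }
})

test_that("QC keeps good SNPs and drops by missingness, MAF and HWE", {
  set.seed(4)
  spec <- snp_sim_spec(c("ok", "rare"), f_u = c(0.3, 0.002), target_or = 1)
  gm <- simulate_genotypes(100, 200, spec, seed = 5)
  # add an all-missing SNP and a planted HWE violation (all hets in controls)
  calls <- cbind(gm$calls,
                 allmiss = NA_integer_,
                 hwe_bad = c(sample(0:2, 100, replace = TRUE),
                             rep(1L, 200)))
  gm2 <- genotype_matrix(calls, gm$groups)
  qc <- qc_filter(gm2, "HC")
  rep_ <- qc$report
  expect_true("ok" %in% qc$kept)
  expect_false("allmiss" %in% qc$kept)
  expect_equal(rep_$reason[rep_$snp_id == "allmiss"], "missing")
  expect_false("rare" %in% qc$kept)
  expect_equal(rep_$reason[rep_$snp_id == "rare"], "maf")
  expect_false("hwe_bad" %in% qc$kept)
  expect_equal(rep_$reason[rep_$snp_id == "hwe_bad"], "hwe")
})

test_that("association scan filters at alpha, sorts by p and recovers effects", {
  spec <- snp_sim_spec(sprintf("rs%02d", 1:20), f_u = 0.3,
                       target_or = c(2.5, rep(1, 19)))
  gm <- simulate_genotypes(500, 500, spec, seed = 6)
  res <- run_association(gm, "CASE", "HC", alpha = 0.05)
  expect_true("rs01" %in% res$snp_id)
  hit <- res[res$snp_id == "rs01", ]
  expect_gt(hit$or_, 2.0)
  expect_lt(hit$or_, 3.1)
  expect_true(all(res$p <= 0.05))
  expect_true(!is.unsorted(res$p))
  all_res <- run_association(gm, "CASE", "HC", alpha = 1.0)
  expect_equal(nrow(all_res), 20)
  expect_true(all(all_res$ci_low <= all_res$or_ &
                    all_res$or_ <= all_res$ci_high, na.rm = TRUE))
  expect_error(run_association(gm, "CASE", "XX"), "group label")
})

test_that("null simulation keeps roughly alpha of SNPs", {
  spec <- snp_sim_spec(sprintf("s%04d", 1:2000), f_u = 0.3, target_or = 1)
  gm <- simulate_genotypes(200, 200, spec, seed = 8)
  res <- run_association(gm, "CASE", "HC", alpha = 0.05)
  rate <- nrow(res) / 2000
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
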