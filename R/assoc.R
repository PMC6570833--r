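#' Allele counts for a case-control contrast at one SNP
#'
#' Tallies the 2x2 allele-count table behind the allelic test: `a` copies of
#' allele 1 and `b` of allele 2 among affected samples, `c` and `d` likewise
#' among unaffected. Missing genotypes are excluded, so `a + b` is twice the
#' number of called affected genotypes.
#'
#' @param x a [genotype_matrix()].
#' @param snp SNP identifier (column of `x`).
#' @param affected,unaffected group labels of the two compared groups.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
count_alleles <- function(x, snp, affected, unaffected) {
  for (g in c(affected, unaffected))
    if (!g %in% x$groups) gp_stop("group label not present: ", g)
  if (!snp %in% colnames(x$calls)) gp_stop("unknown SNP: ", snp)
  g_aff <- x$calls[x$groups == affected, snp]
  g_un <- x$calls[x$groups == unaffected, snp]
  n_aff <- sum(!is.na(g_aff)); n_un <- sum(!is.na(g_un))
  if (n_aff == 0 || n_un == 0)
    gp_stop("zero called genotypes in a group for SNP ", snp)
  a <- sum(g_aff, na.rm = TRUE)
  c_ <- sum(g_un, na.rm = TRUE)
  c(a = as.integer(a), b = as.integer(2L * n_aff - a),
    c = as.integer(c_), d = as.integer(2L * n_un - c_))
}

#' Pearson chi-square statistic for a 2x2 allele-count table
#'
#' The 1-df basic allelic test statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`, without
#' continuity correction.
#'
#' @param t numeric vector `c(a, b, c, d)` of non-negative counts.
#' @return list with `chi2` and `df = 1`.
#' @export
allelic_chi2 <- function(t) {
  t <- as.numeric(t)
  a <- t[1]; b <- t[2]; c_ <- t[3]; d <- t[4]
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0))
    gp_stop("undefined statistic: zero margin in allele-count table")
  list(chi2 = n * (a * d - b * c_)^2 / prod(margins), df = 1L)
}

#' Upper-tail chi-square probability
#'
#' Asymptotic p-value of a chi-square statistic; for 1 df this equals
#' `2 (1 - Phi(sqrt(x)))`.
#'
#' @param x non-negative statistic.
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability in `(0, 1]`.
#' @export
chi2_sf <- function(x, df = 1) {
  if (any(x < 0)) gp_stop("chi-square statistic must be non-negative")
  if (any(df < 1)) gp_stop("df must be >= 1")
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Allelic odds ratio with 95\% confidence interval
#'
#' Cross-product odds ratio `(a d)/(b c)` for allele 1 versus allele 2, with
#' a log-scale normal-approximation confidence interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With a zero cell the
#' quotient is reported literally (`0` for a zero numerator, `Inf` for a zero
#' denominator, `NaN` for 0/0) and the CI bounds are `NA`; setting
#' `haldane = TRUE` instead adds 0.5 to every cell first.
#'
#' @param t numeric vector `c(a, b, c, d)`.
#' @param conf confidence level (default 0.95).
#' @param haldane apply the 0.5 continuity correction to all cells.
#' @return list with `or_`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(t, conf = 0.95, haldane = FALSE) {
  t <- as.numeric(t)
  if (haldane) t <- t + 0.5
  a <- t[1]; b <- t[2]; c_ <- t[3]; d <- t[4]
  or_ <- (a * d) / (b * c_)
  if (any(t == 0)) {
    if (b * c_ > 0 && a * d == 0) or_ <- 0
    return(list(or_ = or_, ci_low = NA_real_, ci_high = NA_real_))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or_ = or_, ci_low = exp(log(or_) - z * se),
       ci_high = exp(log(or_) + z * se))
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test of HWE conditional on the observed allele counts:
#' the p-value sums the probabilities of every heterozygote count (with the
#' same allele totals and parity) whose conditional probability does not
#' exceed that of the observed configuration.
#'
#' @param n_hom1 count of allele-1 homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_hom2 count of allele-2 homozygotes.
#' @return exact two-sided p-value in `(0, 1]`.
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts)))
    gp_stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) gp_stop("all genotype counts are zero")
  n1 <- 2 * n_hom1 + n_het              # copies of allele 1
  if (n1 == 0 || n1 == 2 * n) return(1) # monomorphic: single configuration
  hets <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  # log P(het | n, n1) up to the shared normalizing constant
  logp <- vapply(hets, function(h) {
    h1 <- (n1 - h) / 2; h2 <- n - h - h1
    h * log(2) - lfactorial(h1) - lfactorial(h) - lfactorial(h2)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[hets == n_het]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Per-SNP quality control
#'
#' A SNP is kept iff its missing rate (all samples) is at most
#' `max_snp_missing_rate`, its minor allele frequency (all samples) is at
#' least `min_maf`, and its HWE exact-test p-value in the control group is at
#' least `min_hwe_p`. Defaults are the conventional GWAS settings.
#'
#' @param x a [genotype_matrix()].
#' @param control_group label of the control group used for the HWE test.
#' @param max_snp_missing_rate maximum per-SNP missing-call fraction.
#' @param min_maf minimum minor allele frequency.
#' @param min_hwe_p minimum HWE exact p-value in controls.
#' @return list with `kept` (character vector of SNP IDs) and `report`
#'   (data.frame with per-SNP `missing_rate`, `maf`, `hwe_p`, `kept`,
#'   `reason`).
#' @export
qc_filter <- function(x, control_group,
                      max_snp_missing_rate = 0.05,
                      min_maf = 0.01,
                      min_hwe_p = 1e-6) {
  if (!control_group %in% x$groups)
    gp_stop("group label not present: ", control_group)
  calls <- x$calls
  ctrl <- calls[x$groups == control_group, , drop = FALSE]
  snp_ids <- colnames(calls)
  miss <- colMeans(is.na(calls))
  f1 <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(f1, 1 - f1)
  maf[is.nan(maf)] <- 0
  hwe_p <- vapply(seq_along(snp_ids), function(j) {
    g <- ctrl[, j]; g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact(sum(g == 2), sum(g == 1), sum(g == 0))
  }, 0)
  kept <- miss <= max_snp_missing_rate & maf >= min_maf &
    (!is.na(hwe_p) & hwe_p >= min_hwe_p)
  reason <- rep("", length(snp_ids))
  reason[is.na(hwe_p) | hwe_p < min_hwe_p] <- "hwe"
  reason[maf < min_maf] <- "maf"
  reason[miss > max_snp_missing_rate] <- "missing"
  list(kept = snp_ids[kept],
       report = data.frame(snp_id = snp_ids, missing_rate = miss, maf = maf,
                           hwe_p = hwe_p, kept = kept, reason = reason,
                           row.names = NULL))
}

#' Case-control allelic association scan
#'
#' Runs the 1-df allelic chi-square test, allele frequencies, and allele-1
#' odds ratio with 95\% CI for every SNP, and returns the SNPs significant at
#' `alpha`, sorted by ascending p-value (ties broken by rsID). A
#' Benjamini-Hochberg adjusted p-value over all tested SNPs is reported for
#' information; filtering uses the raw p-value only.
#'
#' @param x a [genotype_matrix()] (already QC-filtered; see [qc_filter()]).
#' @param affected,unaffected group labels of the contrast.
#' @param alpha retain SNPs with raw `p <= alpha` (default 0.05).
#' @param snps optional subset of SNP IDs to test.
#' @return an `assoc_result` data.frame with columns `snp_id`, `locus`,
#'   `chrom`, `a1`, `a2`, `f_a`, `f_u`, `chi2`, `df`, `p`, `p_bh`, `or_`,
#'   `ci_low`, `ci_high`.
#' @export
run_association <- function(x, affected, unaffected, alpha = 0.05,
                            snps = NULL) {
  for (g in c(affected, unaffected))
    if (!g %in% x$groups) gp_stop("group label not present: ", g)
  snp_ids <- snps %||% colnames(x$calls)
  res <- lapply(snp_ids, function(s) {
    t <- count_alleles(x, s, affected, unaffected)
    chi <- tryCatch(allelic_chi2(t), gwaspathnet_error = function(e) NULL)
    or_ <- odds_ratio(t)
    meta <- x$snps[x$snps$snp_id == s, ]
    data.frame(snp_id = s, locus = meta$locus, chrom = meta$chrom,
               a1 = meta$a1, a2 = meta$a2,
               f_a = t["a"] / (t["a"] + t["b"]),
               f_u = t["c"] / (t["c"] + t["d"]),
               chi2 = if (is.null(chi)) NA_real_ else chi$chi2, df = 1L,
               p = if (is.null(chi)) NA_real_ else chi2_sf(chi$chi2, 1),
               or_ = or_$or_, ci_low = or_$ci_low, ci_high = or_$ci_high,
               row.names = NULL)
  })
  res <- do.call(rbind, res)
  res$p_bh <- p.adjust(res$p, method = "BH")
  res <- res[!is.na(res$p) & res$p <= alpha, , drop = FALSE]
  res <- res[order(res$p, res$snp_id), , drop = FALSE]
  res <- res[c("snp_id", "locus", "chrom", "a1", "a2", "f_a", "f_u",
               "chi2", "df", "p", "p_bh", "or_", "ci_low", "ci_high")]
  rownames(res) <- NULL
  attr(res, "contrast") <- c(affected = affected, unaffected = unaffected)
  attr(res, "alpha") <- alpha
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' @export
print.assoc_result <- function(x, digits = 4, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Allelic association: %s vs %s (alpha = %g)\n",
              ct["affected"], ct["unaffected"], attr(x, "alpha")))
  cat(nrow(x), "significant SNP(s)\n")
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
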