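#' Case allele frequency implied by a control frequency and allelic odds ratio
#'
#' Inverts the allelic odds-ratio definition:
#' `f_A = OR * f_U / (1 - f_U + OR * f_U)`.
#'
#' @param f_u control allele-1 frequency in `(0, 1)`.
#' @param target_or allelic odds ratio (> 0).
#' @return case allele-1 frequency.
#' @export
case_frequency <- function(f_u, target_or) {
  if (any(f_u <= 0 | f_u >= 1)) gp_stop("f_u must lie in (0, 1)")
  if (any(target_or <= 0)) gp_stop("target_or must be > 0")
  target_or * f_u / (1 - f_u + target_or * f_u)
}

#' Per-SNP simulation specification
#'
#' @param snp_id rsID-style identifiers.
#' @param f_u control allele-1 frequencies.
#' @param target_or allelic odds ratios (1 = null SNP).
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @return data.frame spec, one row per SNP.
#' @export
snp_sim_spec <- function(snp_id, f_u, target_or = 1, missing_rate = 0) {
  spec <- data.frame(snp_id = as.character(snp_id), f_u = f_u,
                     target_or = target_or, missing_rate = missing_rate)
  if (any(spec$f_u <= 0 | spec$f_u >= 1)) gp_stop("f_u must lie in (0, 1)")
  if (any(spec$target_or <= 0)) gp_stop("target_or must be > 0")
  if (any(spec$missing_rate < 0 | spec$missing_rate >= 1))
    gp_stop("missing_rate must lie in [0, 1)")
  if (anyDuplicated(spec$snp_id)) gp_stop("duplicated snp_id in spec")
  spec
}

#' A simulation spec mirroring the packaged association table
#'
#' One row per distinct SNP of a phenotype block of the packaged per-SNP
#' association table, using its control allele frequencies and odds ratios
#' as simulation targets.
#'
#' @param phenotype phenotype block label (default `"IBD"`).
#' @param missing_rate per-call missing probability.
#' @return a [snp_sim_spec()] data.frame.
#' @export
table2_sim_spec <- function(phenotype = "IBD", missing_rate = 0.01) {
  tab <- read_table2(phenotype)
  tab <- tab[!duplicated(tab$snp_id), ]
  f_u <- pmin(pmax(tab$f_u, 0.005), 0.995)
  or_ <- ifelse(tab$or <= 0, 0.05, tab$or) # a printed OR of 0 cannot be a
  snp_sim_spec(tab$snp_id, f_u, or_, missing_rate) # generative frequency
}

#' Simulate case-control genotypes under Hardy-Weinberg equilibrium
#'
#' For each SNP, case genotypes are Binomial(2, f_A) and control genotypes
#' Binomial(2, f_U) draws (HWE within each group), with
#' `f_A = case_frequency(f_U, OR)`; calls are then masked completely at
#' random at the SNP's missing rate. Fully reproducible from `seed`.
#'
#' @param n_case,n_ctrl numbers of case and control samples.
#' @param spec a [snp_sim_spec()] data.frame.
#' @param seed integer RNG seed (required).
#' @param case_label,control_label group labels (defaults `"CASE"`, `"HC"`).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_case, n_ctrl, spec, seed,
                               case_label = "CASE", control_label = "HC") {
  if (n_case < 1 || n_ctrl < 1) gp_stop("sample sizes must be positive")
  if (missing(seed)) gp_stop("seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_case + n_ctrl
  m <- nrow(spec)
  f_a <- case_frequency(spec$f_u, spec$target_or)
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    g <- c(rbinom(n_case, 2, f_a[j]), rbinom(n_ctrl, 2, spec$f_u[j]))
    if (spec$missing_rate[j] > 0)
      g[runif(n) < spec$missing_rate[j]] <- NA_integer_
    calls[, j] <- g
  }
  samples <- c(sprintf("case_%04d", seq_len(n_case)),
               sprintf("ctrl_%04d", seq_len(n_ctrl)))
  dimnames(calls) <- list(samples, spec$snp_id)
  groups <- setNames(rep(c(case_label, control_label), c(n_case, n_ctrl)),
                     samples)
  snps <- data.frame(snp_id = spec$snp_id, chrom = NA_character_,
                     locus = NA_character_, a1 = "A", a2 = "B")
  genotype_matrix(calls, groups, snps)
}

#' Network simulation specification (planted-partition graph)
#'
#' @param module_sizes integer vector of module sizes.
#' @param p_in within-module edge probability (default 0.8).
#' @param p_out between-module edge probability (default 0.02).
#' @param conf_in_range within-module confidence range, above the 0.400
#'   threshold (default `c(0.45, 0.95)`).
#' @param conf_out_below fraction of between-module edges whose confidence
#'   falls below 0.400 and is thus removed by thresholding (default 0.5).
#' @return list spec.
#' @export
network_sim_spec <- function(module_sizes = c(10, 10, 10, 10),
                             p_in = 0.8, p_out = 0.02,
                             conf_in_range = c(0.45, 0.95),
                             conf_out_below = 0.5) {
  if (!(p_out <= p_in && p_in <= 1 && p_out >= 0))
    gp_stop("need 0 <= p_out <= p_in <= 1")
  list(module_sizes = module_sizes, p_in = p_in, p_out = p_out,
       conf_in_range = conf_in_range, conf_out_below = conf_out_below)
}

#' Simulate a modular protein-association table
#'
#' Planted-partition graph over `sum(module_sizes)` proteins: node pairs in
#' the same module are linked with probability `p_in` and carry confidences
#' drawn uniformly from `conf_in_range` (above the 0.400 threshold); pairs in
#' different modules are linked with probability `p_out`, and a fraction
#' `conf_out_below` of those edges get confidences below 0.400 (so standard
#' thresholding removes them). The planted module of each protein is
#' recorded in the `module` attribute.
#'
#' @param spec a [network_sim_spec()] list.
#' @param seed integer RNG seed (required).
#' @return an `interaction_table` with a `module` attribute (named integer
#'   vector over all simulated proteins).
#' @export
simulate_ppa <- function(spec, seed) {
  if (missing(seed)) gp_stop("seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sizes <- spec$module_sizes
  n <- sum(sizes)
  module <- rep(seq_along(sizes), sizes)
  prot <- sprintf("P%03d", seq_len(n))
  names(module) <- prot
  pairs <- combn(n, 2)
  same <- module[pairs[1, ]] == module[pairs[2, ]]
  p_edge <- ifelse(same, spec$p_in, spec$p_out)
  present <- runif(ncol(pairs)) < p_edge
  i <- pairs[1, present]; j <- pairs[2, present]; within <- same[present]
  conf <- numeric(length(i))
  conf[within] <- runif(sum(within), spec$conf_in_range[1],
                        spec$conf_in_range[2])
  n_out <- sum(!within)
  if (n_out) {
    below <- runif(n_out) < spec$conf_out_below
    cf <- numeric(n_out)
    cf[below] <- runif(sum(below), 0.15, 0.399)
    cf[!below] <- runif(sum(!below), 0.401, 0.6)
    conf[!within] <- cf
  }
  tab <- interaction_table(data.frame(protein_a = prot[i],
                                      protein_b = prot[j],
                                      combined_score = conf))
  attr(tab, "module") <- module
  tab
}

#' Simulate a gene-set database with one planted enriched set
#'
#' Builds `n_sets` gene sets over a synthetic gene universe. One set (the
#' planted one, `set_id` `"PLANTED"` unless `k = 0`, in which case it shares
#' nothing with the query) contains exactly `k` of the query genes; every
#' background set shares at most one query gene by construction.
#'
#' @param n_sets total number of sets.
#' @param set_size_range integer range of set sizes (default `c(10, 30)`).
#' @param query character vector of query gene symbols.
#' @param k planted overlap between the query and the planted set.
#' @param seed integer RNG seed (required).
#' @return a `gene_set_db` with attribute `planted` naming the planted set.
#' @export
simulate_genesets <- function(n_sets, set_size_range = c(10, 30), query, k,
                              seed) {
  if (missing(seed)) gp_stop("seed is required")
  query <- unique(as.character(query))
  if (k > length(query)) gp_stop("overlap k exceeds query size")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pool <- sprintf("BG%04d", seq_len(2000))
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    if (s == 1) {
      if (k > sizes[s]) sizes[s] <- k
      planted_genes <- sample(query, k)
      sets[[s]] <- c(planted_genes, sample(pool, sizes[s] - k))
    } else {
      # background sets share at most one query gene
      share <- sample(0:1, 1)
      qg <- if (share && length(query)) sample(query, 1) else character()
      sets[[s]] <- c(qg, sample(pool, sizes[s] - length(qg)))
    }
  }
  names(sets) <- c("PLANTED", sprintf("SET%03d", seq_len(n_sets - 1)))
  db <- gene_set_db(sets)
  attr(db, "planted") <- "PLANTED"
  db
}

# save/restore the global RNG state so generators are pure in their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
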