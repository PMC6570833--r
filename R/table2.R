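#' Published per-phenotype SNP association results (packaged fixture)
#'
#' Returns the packaged transcription of the study's per-SNP association
#' table for a Greek IBD cohort: for each phenotype contrast against healthy
#' controls (IBD, CD, UC, the CD behaviour subphenotypes B1/B2/B3 and the UC
#' extent subphenotypes E1/E2/E3), the SNP metadata, allele-1 frequencies in
#' affected (`f_a`) and unaffected (`f_u`) individuals (as fractions), the
#' 1-df allelic chi-square statistic, its asymptotic p-value, and the
#' allele-1 odds ratio.
#'
#' Four rsIDs printed truncated in the CD block are normalized to their full
#' dbSNP identifiers by matching locus and control allele frequency against
#' the other blocks: `rs1730982` -> `rs17309827`, `rs1076165` ->
#' `rs10761659`, `rs1723465` -> `rs17234657`, `rs1252919` -> `rs12529198`.
#' The as-printed identifier is retained in `snp_id_raw`.
#'
#' @param phenotype optional phenotype label (e.g. `"CD"`); `NULL` returns
#'   all rows.
#' @return a data.frame with columns `phenotype`, `locus`, `chrom`,
#'   `snp_id_raw`, `snp_id`, `a1`, `f_a`, `f_u`, `a2`, `chi2`, `p`, `or`.
#' @export
read_table2 <- function(phenotype = NULL) {
  path <- system.file("extdata", "table2_snps.tsv", package = "gwaspathnet",
                      mustWork = TRUE)
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  tab$f_a <- tab$f_a_pct / 100
  tab$f_u <- tab$f_u_pct / 100
  tab <- tab[c("phenotype", "locus", "chrom", "snp_id_raw", "snp_id",
               "a1", "f_a", "f_u", "a2", "chi2", "p", "or")]
  if (!is.null(phenotype)) {
    if (!phenotype %in% tab$phenotype)
      gp_stop("unknown phenotype: ", phenotype)
    tab <- tab[tab$phenotype == phenotype, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Per-phenotype SNP identifier sets from the packaged association table
#'
#' Convenience accessor for set comparisons: the normalized rsIDs of the
#' significant SNPs of each phenotype block.
#'
#' @param phenotypes character vector of phenotype labels; default all.
#' @return named list of character vectors of normalized rsIDs.
#' @export
table2_snp_sets <- function(phenotypes = NULL) {
  tab <- read_table2()
  if (is.null(phenotypes)) phenotypes <- unique(tab$phenotype)
  setNames(lapply(phenotypes, function(ph) {
    unique(tab$snp_id[tab$phenotype == ph])
  }), phenotypes)
}

#' Per-phenotype gene (locus) sets from the packaged association table
#'
#' The locus symbols carrying each phenotype's significant SNPs, used as the
#' gene lists feeding pathway and network analysis. Unannotated loci (the
#' `U*` placeholders and numeric region labels) can be dropped.
#'
#' @param phenotypes character vector of phenotype labels; default all.
#' @param drop_unannotated drop placeholder loci that are not gene symbols.
#' @return named list of character vectors of locus symbols.
#' @export
table2_gene_sets <- function(phenotypes = NULL, drop_unannotated = TRUE) {
  tab <- read_table2()
  if (is.null(phenotypes)) phenotypes <- unique(tab$phenotype)
  setNames(lapply(phenotypes, function(ph) {
    loci <- unique(tab$locus[tab$phenotype == ph])
    if (drop_unannotated)
      loci <- loci[!grepl("^U[0-9]+$|^[0-9]", loci)]
    loci
  }), phenotypes)
}
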