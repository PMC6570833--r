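#' Construct a genotype matrix
#'
#' Container for a samples-by-SNPs panel of allele-1 dosage calls with group
#' labels (phenotype / subphenotype) per sample and per-SNP metadata. Calls
#' count copies of allele 1 (the minor allele), so each cell is 0, 1, 2 or
#' `NA` for a missing call.
#'
#' @param calls integer matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`. Row and column names give sample and SNP IDs.
#' @param groups character vector of group labels, one per sample (named by
#'   sample ID or in row order).
#' @param snps data.frame of SNP metadata with columns `snp_id`, and
#'   optionally `chrom`, `locus`, `a1`, `a2`. Defaults to the column names
#'   of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `groups`, `snps`, `calls`.
#' @export
genotype_matrix <- function(calls, groups, snps = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- rownames(calls)
  if (is.null(samples)) gp_stop("calls must have sample row names")
  if (anyDuplicated(samples))
    gp_stop("duplicated sample ID: ", samples[duplicated(samples)][1])
  if (is.null(colnames(calls))) gp_stop("calls must have SNP column names")
  if (is.null(snps)) snps <- data.frame(snp_id = colnames(calls))
  snps <- normalize_snp_meta(snps)
  if (!identical(snps$snp_id, colnames(calls)))
    gp_stop("dimension mismatch: snps metadata does not match call columns")
  if (anyDuplicated(snps$snp_id))
    gp_stop("duplicated SNP ID: ", snps$snp_id[duplicated(snps$snp_id)][1])
  if (!is.null(names(groups))) {
    if (!all(samples %in% names(groups)))
      gp_stop("every sample needs a group label")
    groups <- groups[samples]
  } else if (length(groups) != length(samples)) {
    gp_stop("dimension mismatch: ", length(groups), " group labels for ",
            length(samples), " samples")
  }
  groups <- as.character(groups)
  names(groups) <- samples
  if (anyNA(groups)) gp_stop("every sample needs a group label")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) gp_stop("genotype calls must be 0, 1, 2 or NA")
  structure(list(samples = samples, groups = groups, snps = snps,
                 calls = calls),
            class = "genotype_matrix")
}

normalize_snp_meta <- function(snps) {
  if (!"snp_id" %in% names(snps)) gp_stop("snps needs a snp_id column")
  for (col in c("chrom", "locus", "a1", "a2"))
    if (!col %in% names(snps)) snps[[col]] <- NA_character_
  snps <- snps[c("snp_id", "chrom", "locus", "a1", "a2")]
  snps[] <- lapply(snps, as.character)
  same <- !is.na(snps$a1) & !is.na(snps$a2) & snps$a1 == snps$a2
  if (any(same)) gp_stop("a1 must differ from a2 for SNP ", snps$snp_id[same][1])
  rownames(snps) <- NULL
  snps
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$snps), "SNPs\n")
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of missing genotype calls
#' @param x a [genotype_matrix()]
#' @return integer count of `NA` calls.
#' @export
n_missing <- function(x) sum(is.na(x$calls))

#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `"tsv"`: a header row `sample`, `group`, then
#' one rsID per column; cells are allele-1 dosages `0/1/2` or `NA`. Unknown
#' tokens are converted to missing with a warning giving their count.
#' `"pedmap"`: a minimal PED/MAP pair (`path` is the prefix of `<prefix>.ped`
#' and `<prefix>.map`); the PED family ID column carries the group label and
#' `0` marks a missing allele. Alleles are recoded to allele-1 dosage, where
#' allele 1 is the rarer allele over the whole panel (ties broken
#' alphabetically).
#'
#' @param path file path (TSV) or PED/MAP prefix.
#' @param dialect `"tsv"` or `"pedmap"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "pedmap")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_genotypes_tsv(path) else read_genotypes_pedmap(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) gp_stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, comment.char = "")
  if (ncol(raw) < 3 || !identical(tolower(names(raw)[1:2]), c("sample", "group")))
    gp_stop("malformed header in ", path,
            ": expected columns sample, group, <rsIDs...> (line 1)")
  if (anyDuplicated(raw[[1]])) {
    d <- which(duplicated(raw[[1]]))[1]
    gp_stop("duplicated sample ID '", raw[[1]][d], "' (line ", d + 1L, ")")
  }
  cells <- as.matrix(raw[, -(1:2), drop = FALSE])
  known <- cells %in% c("0", "1", "2", "NA") | is.na(cells)
  if (!all(known)) {
    warning(sum(!known), " unknown genotype token(s) set to missing",
            call. = FALSE)
    cells[!known] <- NA
  }
  calls <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells),
                                   dimnames = list(raw[[1]], colnames(cells))))
  genotype_matrix(calls, setNames(raw[[2]], raw[[1]]))
}

read_genotypes_pedmap <- function(prefix) {
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) gp_stop("file not found: ", p)
  map <- read.table(map_path, sep = "\t", header = FALSE,
                    colClasses = "character")
  if (ncol(map) < 4) gp_stop("malformed MAP file: expected 4 columns")
  names(map)[1:4] <- c("chrom", "snp_id", "cm", "pos")
  ped <- read.table(ped_path, sep = "\t", header = FALSE,
                    colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp)
    gp_stop("dimension mismatch: PED has ", ncol(ped), " columns but MAP lists ",
            n_snp, " SNPs")
  if (anyDuplicated(ped[[2]]))
    gp_stop("duplicated sample ID '", ped[[2]][duplicated(ped[[2]])][1], "'")
  samples <- ped[[2]]
  groups <- setNames(ped[[1]], samples)
  calls <- matrix(NA_integer_, nrow(ped), n_snp,
                  dimnames = list(samples, map$snp_id))
  a1 <- a2 <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al1 <- ped[[6 + 2 * j - 1]]; al2 <- ped[[6 + 2 * j]]
    obs <- c(al1, al2); obs <- obs[obs != "0"]
    lev <- sort(unique(obs))
    if (length(lev) == 0) { a1[j] <- "N"; a2[j] <- "M"; next }
    counts <- table(factor(obs, levels = lev))
    # allele 1 = rarer allele over the panel; alphabetical tie-break
    minor <- lev[order(counts, lev)][1]
    major <- if (length(lev) > 1) setdiff(lev, minor)[1] else "0"
    a1[j] <- minor; a2[j] <- major
    miss <- al1 == "0" | al2 == "0"
    calls[, j] <- ifelse(miss, NA_integer_,
                         (al1 == minor) + (al2 == minor))
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                     locus = NA_character_, a1 = a1, a2 = a2)
  genotype_matrix(calls, groups, snps)
}

#' Read a SNP annotation table
#'
#' TSV with columns `snp_id`, and optionally `chrom`, `locus`, `a1`, `a2` —
#' the panel metadata (rsID, chromosome, carrying gene/locus, minor and major
#' allele) that the genotype TSV dialect does not carry itself.
#'
#' @param path TSV file path.
#' @return data.frame of SNP metadata.
#' @export
read_snp_annotation <- function(path) {
  if (!file.exists(path)) gp_stop("file not found: ", path)
  normalize_snp_meta(read.table(path, sep = "\t", header = TRUE,
                                colClasses = "character",
                                check.names = FALSE))
}

#' Attach SNP annotation to a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param annotation data.frame from [read_snp_annotation()]; rows are
#'   matched to the panel by `snp_id`, unknown SNPs in the annotation are
#'   ignored, unannotated panel SNPs keep `NA` metadata.
#' @return the annotated [genotype_matrix()].
#' @export
annotate_genotypes <- function(x, annotation) {
  annotation <- normalize_snp_meta(annotation)
  idx <- match(x$snps$snp_id, annotation$snp_id)
  hit <- !is.na(idx)
  for (col in c("chrom", "locus", "a1", "a2"))
    x$snps[[col]][hit] <- annotation[[col]][idx[hit]]
  x
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()]. For the `"pedmap"` dialect, `path` is the
#' output prefix and allele codes come from the SNP metadata (`a1`/`a2`,
#' falling back to `A`/`B` when absent).
#'
#' @param x a [genotype_matrix()].
#' @param path output path or PED/MAP prefix.
#' @param dialect `"tsv"` or `"pedmap"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = c("tsv", "pedmap")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- data.frame(sample = x$samples, group = unname(x$groups),
                      x$calls, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  a1 <- ifelse(is.na(x$snps$a1), "A", x$snps$a1)
  a2 <- ifelse(is.na(x$snps$a2), "B", x$snps$a2)
  n <- length(x$samples); m <- nrow(x$snps)
  geno <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    g <- x$calls[, j]
    geno[, 2 * j - 1] <- ifelse(is.na(g), "0", ifelse(g >= 1, a1[j], a2[j]))
    geno[, 2 * j] <- ifelse(is.na(g), "0", ifelse(g == 2, a1[j], a2[j]))
  }
  ped <- cbind(unname(x$groups), x$samples, "0", "0", "0", "-9", geno)
  write.table(ped, paste0(path, ".ped"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  map <- cbind(ifelse(is.na(x$snps$chrom), "0", x$snps$chrom),
               x$snps$snp_id, "0", seq_len(m))
  write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
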