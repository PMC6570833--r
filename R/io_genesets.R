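#' Read a gene-set database in GMT format
#'
#' Each line is `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Member lists are deduplicated preserving first occurrence; file order of
#' sets is preserved.
#'
#' @param path GMT file path.
#' @return a `gene_set_db`: named list of character vectors of member genes,
#'   with a `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) gp_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short))
    gp_stop("malformed GMT line ", which(short)[1], ": fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    gp_stop("duplicated set_id: ", ids[duplicated(ids)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  gene_set_db(sets, vapply(fields, `[[`, "", 2L))
}

#' Construct a gene-set database
#' @param sets named list of character vectors (member gene symbols).
#' @param descriptions optional character vector of set descriptions.
#' @return a `gene_set_db` object.
#' @export
gene_set_db <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    gp_stop("every gene set needs a set_id")
  if (anyDuplicated(names(sets)))
    gp_stop("duplicated set_id: ", names(sets)[duplicated(names(sets))][1])
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- vapply(sets, length, 0L) == 0L
  if (any(empty)) gp_stop("empty member list for set ", names(sets)[empty][1])
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  sizes <- lengths(x)
  cat("gene_set_db:", length(x), "sets;",
      length(unique(unlist(x))), "distinct genes; set sizes ",
      min(sizes), "-", max(sizes), "\n", sep = " ")
  invisible(x)
}

#' Write a gene-set database in GMT format
#' @param db a `gene_set_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  desc <- attr(db, "descriptions") %||% setNames(rep("", length(db)), names(db))
  lines <- vapply(names(db), function(id) {
    paste(c(id, desc[[id]], db[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
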