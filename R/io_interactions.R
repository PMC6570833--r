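#' Read a protein-protein association table
#'
#' Reads a STRING-style TSV with columns `protein1`, `protein2`,
#' `combined_score` (extra per-channel score columns are kept but never gate
#' edges). Two score dialects are auto-detected: integers in 0-1000 (divided
#' by 1000) and floats in `[0, 1]`. On load, self-pairs are dropped, duplicate
#' unordered pairs are collapsed to their maximum score, and records below
#' `min_score` are removed.
#'
#' @param path TSV file path.
#' @param min_score minimum combined score kept (default 0.400, the
#'   conventional medium-confidence threshold).
#' @return an `interaction_table`: a data.frame with columns `protein_a`,
#'   `protein_b`, `combined_score` plus any channel columns.
#' @export
read_interactions <- function(path, min_score = 0.400) {
  if (!file.exists(path)) gp_stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(raw)[1:2] <- c("protein_a", "protein_b")
  if (!"combined_score" %in% names(raw))
    gp_stop("malformed interaction table: no combined_score column")
  interaction_table(raw, min_score = min_score)
}

#' Build an interaction table from a data.frame
#'
#' Applies the same normalization as [read_interactions()]: score-scale
#' detection, self-loop removal, unordered-pair deduplication (max score) and
#' thresholding.
#'
#' @param df data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @param min_score minimum combined score kept.
#' @return an `interaction_table` data.frame.
#' @export
interaction_table <- function(df, min_score = 0) {
  score <- as.numeric(df$combined_score)
  if (anyNA(score)) gp_stop("non-numeric combined_score")
  # integer 0-1000 dialect: any score above 1 (and integral) means per-mille
  if (length(score) && max(score) > 1) {
    if (any(score != round(score)) || max(score) > 1000)
      gp_stop("combined_score outside [0,1] and not in the 0-1000 dialect")
    score <- score / 1000
  }
  if (any(score < 0 | score > 1))
    gp_stop("combined_score outside [0,1] after normalization")
  df$combined_score <- score
  df$protein_a <- as.character(df$protein_a)
  df$protein_b <- as.character(df$protein_b)
  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  if (nrow(df)) {
    key <- ifelse(df$protein_a < df$protein_b,
                  paste(df$protein_a, df$protein_b, sep = "\r"),
                  paste(df$protein_b, df$protein_a, sep = "\r"))
    ord <- order(key, -df$combined_score)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
    swap <- df$protein_a > df$protein_b
    tmp <- df$protein_a[swap]
    df$protein_a[swap] <- df$protein_b[swap]
    df$protein_b[swap] <- tmp
  }
  df <- df[df$combined_score >= min_score, , drop = FALSE]
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Write an interaction table as TSV
#' @param x an `interaction_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  out <- as.data.frame(x)
  names(out)[1:2] <- c("protein1", "protein2")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
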