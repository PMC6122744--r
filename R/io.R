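# Readers and writers for the plain-text interchange formats: beta matrix
# TSV (probe rows, sample columns), sample sheet CSV, manifest-style
# annotation TSV, truth TSV, and one-ID-per-line probe/gene lists. All
# writers use fixed numeric formatting (6 significant digits; p/q columns
# in 3-digit scientific) so reruns are byte-identical.

#' Write a beta (or M) matrix as TSV
#'
#' @param mat Probes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_beta_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat),
                   format_num(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a beta matrix TSV written by [write_beta_tsv()]
#'
#' @param path Input path.
#' @return Probes x samples numeric matrix.
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a sample sheet as CSV
#' @param sheet Sample sheet data frame.
#' @param path Output path.
#' @export
write_sample_sheet_csv <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample sheet CSV
#' @param path Input path.
#' @return Data frame.
#' @export
read_sample_sheet_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a probe annotation (or any result table) as TSV
#' @param df Data frame.
#' @param path Output path.
#' @param p_cols Columns rendered in 3-digit scientific notation.
#' @export
write_table_tsv <- function(df, path, p_cols = intersect(
                              c("p", "q", "p_bartlett", "q_bartlett",
                                "p_ttest", "p_enriched", "p_depleted"),
                              colnames(df))) {
  out <- df
  for (cc in colnames(out)) {
    if (is.numeric(out[[cc]])) {
      out[[cc]] <- format_num(out[[cc]], scientific = cc %in% p_cols)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table
#' @param path Input path.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a one-ID-per-line list (probe or gene signature file)
#' @param path Input path.
#' @return Character vector (empty lines dropped).
#' @export
read_id_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Write a one-ID-per-line list
#' @param ids Character vector.
#' @param path Output path.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
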