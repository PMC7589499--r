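#' Write a result table as TSV
#'
#' Writes any of the pipeline's result tables (differential expression,
#' consensus, enrichment, normalization factors) with a header, fixed column
#' order as supplied, and reals rendered with 10 significant digits so a
#' read-back reproduces values well beyond 6 significant digits.
#'
#' @param results a data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  for (col in names(df)) {
    if (is.double(df[[col]]))
      df[[col]] <- formatC(df[[col]], digits = 10, format = "g")
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write results to %s", path))
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path path to a TSV file.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
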