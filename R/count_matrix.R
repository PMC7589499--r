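#' Construct a validated gene-by-library count matrix
#'
#' The central data container for the pipeline: a numeric matrix of
#' non-negative integer read counts with unique gene identifiers as row names
#' and unique library identifiers as column names. All downstream stages
#' (filtering, RLE normalization, the exact test, the GLM) consume this class.
#'
#' @param counts numeric matrix of non-negative integers (genes x libraries).
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param library_ids character vector of unique library identifiers; defaults
#'   to `colnames(counts)`.
#' @return An object of class `count_matrix` (a matrix with dimnames).
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2), c("g1", "g2"), c("lib1", "lib2"))
#' dim(m)
#' @export
count_matrix <- function(counts,
                         gene_ids = rownames(counts),
                         library_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(library_ids))
    format_error("count matrix requires gene and library identifiers")
  gene_ids <- as.character(gene_ids)
  library_ids <- as.character(library_ids)
  if (length(gene_ids) != nrow(counts))
    format_error("number of gene ids does not match number of rows")
  if (length(library_ids) != ncol(counts))
    format_error("number of library ids does not match number of columns")
  if (anyDuplicated(gene_ids))
    format_error("duplicated gene identifiers")
  if (anyDuplicated(library_ids))
    format_error("duplicated library identifiers")
  if (anyNA(counts) || !is.numeric(counts))
    format_error("counts must be numeric and non-missing")
  if (any(counts < 0))
    format_error("negative counts")
  if (any(counts != round(counts)))
    format_error("non-integer counts")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, library_ids)
  class(counts) <- c("count_matrix", class(matrix()))
  counts
}

#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("count_matrix", class(matrix()))
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries (total reads: %s)\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Gene identifiers of a count matrix
#' @param x a `count_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x)

#' Library identifiers of a count matrix
#' @param x a `count_matrix`.
#' @return Character vector of library ids.
#' @export
library_ids <- function(x) colnames(x)

#' Read a count matrix from a tab-separated file
#'
#' Expects a header row of library identifiers, a first column of gene
#' identifiers, and integer cells. Input order of genes and libraries is
#' preserved; `write_counts()` followed by `read_counts()` round-trips exactly.
#'
#' @param path path to a TSV file.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (ncol(tab) < 2) format_error("count file needs a gene column and at least one library")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) format_error("non-numeric cells in count file")
  count_matrix(m, gene_ids = ids, library_ids = colnames(tab)[-1])
}

#' Write a count matrix as a tab-separated file
#'
#' @param counts a [count_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  con <- tryCatch(file(path, "wb"), error = function(e) io_error(conditionMessage(e)))
  on.exit(close(con))
  header <- paste(c("gene_id", colnames(counts)), collapse = "\t")
  body <- paste(rownames(counts),
                apply(format(counts, scientific = FALSE, trim = TRUE), 1L,
                      paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
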