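#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Every term must carry at
#' least one gene; term ids must be unique.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: a named list of
#'   `list(description =, genes =)` entries, one per term, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    format_error(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) format_error("duplicated term ids in GMT")
  sets <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) format_error("GMT term with no genes")
    list(description = f[[2L]], genes = genes)
  })
  names(sets) <- ids
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection as a GMT file
#' @param gsc a `gene_set_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(seq_along(gsc), function(i) {
    paste(c(names(gsc)[i], gsc[[i]]$description, gsc[[i]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), 1L)
  cat(sprintf("gene_set_collection: %d terms, set sizes %d-%d (median %g)\n",
              length(x), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}
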