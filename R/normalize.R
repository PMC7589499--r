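#' Remove genes with low total counts
#'
#' Drops genes whose total read count across the supplied libraries is below
#' `min_total` (default 10, i.e. genes with fewer than 10 reads). Filtering is
#' deliberately a function of the libraries handed in, so each analysis subset
#' (each 4vs4 replicate selection, the full 16-library set) defines its own
#' filtered gene universe.
#'
#' @param counts a [count_matrix()].
#' @param min_total minimum total count for a gene to be retained.
#' @return A [count_matrix()] with the retained genes, order preserved.
#' @export
filter_low_counts <- function(counts, min_total = 10) {
  keep <- rowSums(counts) >= min_total
  counts[keep, , drop = FALSE]
}

#' Relative log expression (RLE) size factors
#'
#' Median-of-ratios normalization. A reference expression level per gene is
#' the geometric mean of its counts across libraries, computed over the genes
#' with strictly positive counts everywhere; each library's raw factor is the
#' median over those genes of count/reference. Factors are rescaled to
#' geometric mean 1. The effective library size pairs each library's
#' size factor with the geometric-mean raw library sum, so that a library
#' sequenced twice as deeply gets twice the effective size.
#'
#' @param counts a [count_matrix()] (typically already filtered).
#' @return A data.frame of class `norm_factors` with columns `library_id`,
#'   `size_factor`, `effective_lib_size`.
#' @export
rle_factors <- function(counts) {
  m <- unclass(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    normalization_error(
      "RLE normalization impossible: no gene has strictly positive counts in every library")
  mp <- m[pos, , drop = FALSE]
  log_ref <- rowMeans(log(mp))
  ratios <- mp / exp(log_ref)
  f <- apply(ratios, 2L, stats::median)
  if (any(!is.finite(f)) || any(f <= 0))
    normalization_error("non-finite or non-positive raw RLE factor")
  s <- f / exp(mean(log(f)))
  lib_sums <- colSums(m)
  eff <- exp(mean(log(lib_sums))) * s
  out <- data.frame(library_id = colnames(m), size_factor = s,
                    effective_lib_size = eff, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' Log2 counts-per-million
#'
#' `log2((count + prior) / (effective_lib_size + 1) * 1e6)`, using the
#' effective library sizes from [rle_factors()].
#'
#' @param counts a [count_matrix()].
#' @param factors a `norm_factors` table for the same libraries, same order.
#' @param prior prior count added to every cell (default 0.5).
#' @return A numeric matrix, same dimnames as `counts`.
#' @export
log_cpm <- function(counts, factors, prior = 0.5) {
  if (!identical(colnames(counts), factors$library_id))
    consistency_error("factors were not computed on these libraries (id mismatch)")
  eff <- factors$effective_lib_size
  log2(sweep(unclass(counts) + prior, 2L, eff + 1, "/") * 1e6)
}
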