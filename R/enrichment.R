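#' Gene-set overrepresentation by the hypergeometric test
#'
#' For each term, counts the overlap k between the DE set and the term within
#' the background universe and computes the one-sided overrepresentation
#' p-value `P(X >= k)` under the hypergeometric distribution with margins
#' (N = background size, K = term genes in background, n = DE genes in
#' background); p-values are BH-adjusted across all tested terms. Terms with
#' no gene in the background are skipped. A two-sided option (Fisher's exact
#' test) is exposed.
#'
#' @param de_genes character vector of DE gene ids (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe (typically all genes
#'   passing the analysis filter; the annotation or the DE set itself are
#'   legitimate alternatives for robustness checks).
#' @param annotation a `gene_set_collection` from [read_gmt()] or
#'   [simulate_annotation()].
#' @param alternative "over" (one-sided overrepresentation, default) or
#'   "two.sided" (Fisher's exact test).
#' @return A data.frame of class `enrichment_result` with one row per tested
#'   term: `term_id`, `description`, `k`, `K`, `n`, `N`, `direction`
#'   ("over"/"under"/"none" by comparing k/n with K/N), `p_value`, `fdr`.
#' @export
fisher_enrichment <- function(de_genes, background, annotation,
                              alternative = c("over", "two.sided")) {
  alternative <- match.arg(alternative)
  de_genes <- unique(de_genes)
  background <- unique(background)
  if (length(setdiff(de_genes, background)))
    input_error("de_genes must be a subset of the background universe")
  N <- length(background)
  n <- length(de_genes)
  de_in <- background %in% de_genes
  rows <- lapply(seq_along(annotation), function(i) {
    term_genes <- intersect(annotation[[i]]$genes, background)
    K <- length(term_genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(term_genes, de_genes))
    p <- if (alternative == "over")
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    else
      stats::fisher.test(matrix(c(k, n - k, K - k, N - K - (n - k)), 2L))$p.value
    data.frame(term_id = names(annotation)[i],
               description = annotation[[i]]$description,
               k = k, K = K, n = n, N = N,
               direction = if (k / max(n, 1) > K / N) "over"
               else if (k / max(n, 1) < K / N) "under" else "none",
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(term_id = character(), description = character(),
                  k = integer(), K = integer(), n = integer(), N = integer(),
                  direction = character(), p_value = numeric(),
                  stringsAsFactors = FALSE)
  out$fdr <- if (nrow(out)) bh_adjust(out$p_value) else numeric()
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two samples with midranks for ties. In `auto` mode
#' the exact null distribution is enumerated when both samples have at most 12
#' observations and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used (the modes of
#' `stats::wilcox.test`).
#'
#' @param x,y numeric vectors (non-empty).
#' @param mode "auto" (default), "exact", or "normal-approx".
#' @return The two-sided p-value.
#' @export
wilcoxon_shift_test <- function(x, y, mode = c("auto", "exact", "normal-approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) domain_error("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "exact" && ties)
    domain_error("exact enumeration requires tie-free samples")
  exact <- switch(mode,
                  exact = TRUE,
                  `normal-approx` = FALSE,
                  auto = max(length(x), length(y)) <= 12 && !ties)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact)$p.value)
}

#' Compare log-fold-change distributions between labelled and unlabelled genes
#'
#' Partitions the fold changes of a DE result table by membership in a gene
#' label set (e.g. immune-annotated genes) and tests for a location shift with
#' the Wilcoxon rank-sum test, on raw LFC or on |LFC|.
#'
#' @param de_results a `de_result` data.frame (columns `gene_id`, `log_fc`).
#' @param gene_labels character vector of labelled gene ids.
#' @param use_abs compare |LFC| instead of signed LFC.
#' @param mode passed to [wilcoxon_shift_test()].
#' @return A list with `shift_direction` ("higher"/"lower"/"none" for the
#'   labelled genes), `p_value`, `median_diff` (labelled minus unlabelled
#'   median), and the partition sizes `n_labelled`, `n_unlabelled`.
#' @export
compare_lfc_distributions <- function(de_results, gene_labels,
                                      use_abs = FALSE, mode = "auto") {
  lab <- de_results$gene_id %in% gene_labels
  if (sum(lab) < 2L || sum(!lab) < 2L)
    domain_error("need at least 2 genes in both the labelled set and its complement")
  v <- if (use_abs) abs(de_results$log_fc) else de_results$log_fc
  p <- wilcoxon_shift_test(v[lab], v[!lab], mode = mode)
  md <- stats::median(v[lab]) - stats::median(v[!lab])
  list(shift_direction = if (md > 0) "higher" else if (md < 0) "lower" else "none",
       p_value = p, median_diff = md,
       n_labelled = sum(lab), n_unlabelled = sum(!lab))
}
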