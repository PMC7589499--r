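#' Fit the consensus differential-expression model
#'
#' The central fitting function. Runs up to three analytical strategies on a
#' gene-by-library count matrix with a nested two-category / multi-site /
#' two-pool design, and combines them into the consensus call:
#'
#' * `fourvfour` - the exhaustive replicate-combination analysis: for every
#'   way of keeping one replicate pool per site, an independent standalone
#'   analysis (refilter, renormalize, re-estimate dispersion, NB conditional
#'   exact test, BH within the combination) tallies how often each gene is
#'   significant;
#' * `eightveight` - all libraries together, with site absorbed as a nested
#'   fixed factor in an NB GLM and the invasion effect tested by likelihood
#'   ratio;
#' * `ranef` - the shared within-site correlation model with empirical-Bayes
#'   moderated t-statistics.
#'
#' A gene is consensus-DE when significant in the 8vs8 analysis and in at
#' least `ceiling(threshold * 2^S)` of the replicate combinations.
#'
#' @param counts a [count_matrix()].
#' @param design a matching single-species [study_design()].
#' @param alpha FDR threshold (default 0.05).
#' @param threshold consensus fraction of combinations (default 0.85).
#' @param min_total low-count filter threshold (default 10).
#' @param prior_df dispersion-shrinkage prior df for the GLM (default 10).
#' @param strategies subset of `c("fourvfour", "eightveight", "ranef")`.
#' @param dispersion_4vs4 dispersion mode for the combination runs
#'   (see [run_4vs4_all()]).
#' @param verbose progress messages for the combination loop.
#' @return An object of class `consensus_de`: a list with `fourvfour`
#'   (`combo_tally`), `eightveight` and `ranef` (`de_result` tables),
#'   `consensus` (`consensus_result` table), `rho`, `alpha`, `threshold`,
#'   `design`, and `n_genes_input`. Any strategy not requested is `NULL`;
#'   the consensus table requires both `fourvfour` and `eightveight` (a
#'   warning is issued otherwise and `consensus` stays `NULL`).
#' @seealso [print.consensus_de()], [summary.consensus_de()],
#'   [plot.consensus_de()], [coef.consensus_de()]
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n_genes = 300, seed = 7))
#' fit <- consensus_de(sim$counts, sim$design)
#' print(fit)
#' }
#' @export
consensus_de <- function(counts, design, alpha = 0.05, threshold = 0.85,
                         min_total = 10, prior_df = 10,
                         strategies = c("fourvfour", "eightveight", "ranef"),
                         dispersion_4vs4 = "tagwise", verbose = FALSE) {
  strategies <- match.arg(strategies, c("fourvfour", "eightveight", "ranef"),
                          several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) parameter_error("alpha must lie in (0, 1)")
  design <- design_species(design)
  if (!all(design$library_id %in% colnames(counts)))
    consistency_error("design contains libraries absent from the count matrix")
  counts <- counts[, design$library_id, drop = FALSE]

  tally <- de8 <- der <- cons <- NULL
  if ("fourvfour" %in% strategies)
    tally <- run_4vs4_all(counts, design, alpha = alpha, min_total = min_total,
                          dispersion = dispersion_4vs4, prior_df = prior_df,
                          verbose = verbose)
  if ("eightveight" %in% strategies)
    de8 <- run_8vs8(counts, design, alpha = alpha, min_total = min_total,
                    prior_df = prior_df)
  if ("ranef" %in% strategies)
    der <- run_ranef(counts, design, alpha = alpha, min_total = min_total)
  if (!is.null(tally) && !is.null(de8)) {
    cons <- combine_calls(tally, de8, der, threshold_frac = threshold,
                          alpha = alpha)
  } else {
    warning("the final consensus call requires both the 4vs4 and 8vs8 strategies",
            call. = FALSE)
  }
  out <- list(fourvfour = tally, eightveight = de8, ranef = der,
              consensus = cons,
              rho = if (is.null(der)) NA_real_ else attr(der, "rho"),
              alpha = alpha, threshold = threshold, design = design,
              n_genes_input = nrow(counts))
  class(out) <- "consensus_de"
  out
}

#' @export
print.consensus_de <- function(x, ...) {
  cat("Consensus differential-expression fit\n")
  cat(sprintf("  libraries: %d (%d sites x 2 pools), alpha = %g\n",
              nrow(x$design), length(unique(x$design$site)), x$alpha))
  if (!is.null(x$eightveight))
    cat(sprintf("  8vs8: %d genes tested, %d DE at FDR < %g\n",
                nrow(x$eightveight), sum(x$eightveight$fdr < x$alpha), x$alpha))
  if (!is.null(x$fourvfour))
    cat(sprintf("  4vs4: %d combinations, %d genes systematically DE\n",
                x$fourvfour$n_combos,
                sum(x$fourvfour$tally == x$fourvfour$n_combos)))
  if (!is.null(x$ranef))
    cat(sprintf("  random-effects: %d DE at FDR < %g (rho = %.3f)\n",
                sum(x$ranef$fdr < x$alpha), x$alpha, x$rho))
  if (!is.null(x$consensus))
    cat(sprintf("  consensus: %d genes DE in 8vs8 AND >= %d/%d combinations\n",
                sum(x$consensus$final_de),
                attr(x$consensus, "consensus_threshold"),
                x$fourvfour$n_combos))
  invisible(x)
}

#' Summary of a consensus DE fit
#' @param object a `consensus_de` object.
#' @param ... unused.
#' @return A list of class `summary.consensus_de` with the per-strategy DE
#'   counts, filtered-universe sizes, threshold arithmetic and the tally
#'   histogram.
#' @export
summary.consensus_de <- function(object, ...) {
  s <- list(
    alpha = object$alpha,
    threshold_frac = object$threshold,
    n_libraries = nrow(object$design),
    n_sites = length(unique(object$design$site)),
    n_genes_input = object$n_genes_input,
    rho = object$rho,
    n_combos = if (!is.null(object$fourvfour)) object$fourvfour$n_combos else NA,
    consensus_threshold = if (!is.null(object$consensus))
      attr(object$consensus, "consensus_threshold") else NA,
    n_tested_8vs8 = if (!is.null(object$eightveight)) nrow(object$eightveight) else NA,
    n_de_8vs8 = if (!is.null(object$eightveight))
      sum(object$eightveight$fdr < object$alpha) else NA,
    n_systematic_4vs4 = if (!is.null(object$fourvfour))
      sum(object$fourvfour$tally == object$fourvfour$n_combos) else NA,
    n_de_ranef = if (!is.null(object$ranef))
      sum(object$ranef$fdr < object$alpha) else NA,
    n_final_de = if (!is.null(object$consensus))
      sum(object$consensus$final_de) else NA,
    tally_histogram = if (!is.null(object$consensus))
      attr(object$consensus, "tally_histogram") else NULL)
  class(s) <- "summary.consensus_de"
  s
}

#' @export
print.summary.consensus_de <- function(x, ...) {
  cat("Consensus DE summary\n")
  cat(sprintf("  design: %d libraries over %d sites; input genes: %d\n",
              x$n_libraries, x$n_sites, x$n_genes_input))
  cat(sprintf("  combinations: %s; consensus needs >= %s significant (%.0f%%)\n",
              x$n_combos, x$consensus_threshold, 100 * x$threshold_frac))
  cat(sprintf("  8vs8: %s tested, %s DE | systematic 4vs4: %s | ranef DE: %s\n",
              x$n_tested_8vs8, x$n_de_8vs8, x$n_systematic_4vs4, x$n_de_ranef))
  cat(sprintf("  final consensus DE genes: %s\n", x$n_final_de))
  invisible(x)
}

#' Tally histogram of a consensus DE fit
#'
#' Bar plot of the number of 4vs4 combinations in which each 8vs8-significant
#' gene was significant - the diagnostic from which the consensus threshold is
#' chosen. The threshold is drawn as a vertical line.
#'
#' @param x a `consensus_de` object with a consensus table.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the histogram data.frame.
#' @export
plot.consensus_de <- function(x, ...) {
  if (is.null(x$consensus)) domain_error("fit has no consensus table to plot")
  h <- attr(x$consensus, "tally_histogram")
  bp <- graphics::barplot(h$n_genes, names.arg = h$n_combos_de,
                          xlab = "combinations significant (of all 4vs4 runs)",
                          ylab = "8vs8-significant genes", border = NA, ...)
  thr <- attr(x$consensus, "consensus_threshold")
  graphics::abline(v = bp[thr + 1L], lty = 2)
  invisible(h)
}

#' Log2 fold changes of a consensus DE fit
#' @param object a `consensus_de` object with an 8vs8 table.
#' @param ... unused.
#' @return Named vector of log2 fold changes (recent vs ancient) from the
#'   8vs8 GLM.
#' @export
coef.consensus_de <- function(object, ...) {
  if (is.null(object$eightveight)) domain_error("fit has no 8vs8 table")
  stats::setNames(object$eightveight$log_fc, object$eightveight$gene_id)
}
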