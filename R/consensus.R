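#' Enumerate all replicate-selection combinations
#'
#' All `2^S` ways of choosing one of the two replicate pools of each site, in
#' deterministic lexicographic order over (site order of first appearance,
#' pool index): the first site is the most significant position and pool 1
#' sorts before pool 2.
#'
#' @param design a single-species [study_design()] with exactly 2 replicate
#'   pools per site.
#' @return A list of character vectors of library ids, one per combination
#'   (each of length S, ordered by site).
#' @export
enumerate_combinations <- function(design) {
  design <- design_species(design)
  sites <- unique(design$site)
  S <- length(sites)
  per_site <- lapply(sites, function(s) {
    rows <- design[design$site == s, , drop = FALSE]
    if (nrow(rows) != 2L || !setequal(rows$pool_index, 1:2))
      design_error(sprintf("site %s does not have exactly 2 replicate pools", s))
    rows$library_id[order(rows$pool_index)]
  })
  # last site varies fastest => lexicographic with site 1 most significant
  grid <- expand.grid(rev(lapply(seq_len(S), function(i) 1:2)),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(S)), drop = FALSE]
  combos <- lapply(seq_len(nrow(grid)), function(k)
    vapply(seq_len(S), function(i) per_site[[i]][grid[k, i]], ""))
  attr(combos, "sites") <- sites
  combos
}

#' Run the exhaustive 4vs4 replicate-combination analysis
#'
#' For every possible selection of one replicate pool per site: subset the
#' libraries, re-apply the low-count filter, recompute RLE factors, estimate
#' the dispersion, run the NB conditional exact test per gene
#' (recent vs ancient), and adjust p-values by Benjamini-Hochberg within the
#' combination. A gene's tally counts the combinations in which it was present
#' after filtering and significant at `fdr < alpha`; filtered-out genes count
#' as non-significant.
#'
#' @param counts a [count_matrix()] over all libraries.
#' @param design matching single-species [study_design()].
#' @param alpha FDR threshold within each combination (default 0.05).
#' @param min_total low-count filter threshold per combination (default 10).
#' @param dispersion "tagwise" (default, shrunk gene-wise estimates) or
#'   "common" per-combination estimation, or a fixed numeric dispersion
#'   reused in every combination.
#' @param prior_df shrinkage prior df when `dispersion = "tagwise"`.
#' @param verbose print progress every 32 combinations.
#' @return A list of class `combo_tally`: `tally` (named per-gene counts over
#'   all genes of `counts`), `n_combos`, `per_combo_n_de`, `alpha`.
#' @export
run_4vs4_all <- function(counts, design, alpha = 0.05, min_total = 10,
                         dispersion = "tagwise", prior_df = 10,
                         verbose = FALSE) {
  design <- design_species(design)
  combos <- enumerate_combinations(design)
  tally <- stats::setNames(integer(nrow(counts)), rownames(counts))
  n_de <- integer(length(combos))
  cat_of_lib <- stats::setNames(design$invasion_category, design$library_id)
  for (k in seq_along(combos)) {
    libs <- combos[[k]]
    sub <- counts[, libs, drop = FALSE]
    sub <- filter_low_counts(sub, min_total)
    if (nrow(sub) == 0L) next
    nf <- rle_factors(sub)
    grp <- factor(cat_of_lib[libs], levels = c("ancient", "recent"))
    phi <- if (is.numeric(dispersion)) dispersion
    else {
      common <- estimate_common_dispersion(sub, nf, grp)
      if (identical(dispersion, "tagwise"))
        estimate_tagwise_dispersions(sub, nf, grp, common, prior_df)$shrunk
      else common
    }
    res <- exact_test_all(sub, grp, nf$effective_lib_size, phi)
    sig <- res$gene_id[bh_adjust(res$p_value) < alpha]
    tally[sig] <- tally[sig] + 1L
    n_de[k] <- length(sig)
    if (verbose && k %% 32L == 0L)
      message(sprintf("4vs4: %d/%d combinations done", k, length(combos)))
  }
  out <- list(tally = tally, n_combos = length(combos),
              per_combo_n_de = n_de, alpha = alpha)
  class(out) <- "combo_tally"
  out
}

#' Run the 8vs8 nested-site GLM analysis
#'
#' Uses all libraries: filter, RLE-normalize, estimate common and shrunk
#' gene-wise dispersions (site as the grouping), then per gene fit the full
#' NB GLM (intercept + invasion indicator + sum-to-zero site contrasts within
#' each category) and the reduced model without the invasion term, and test
#' the invasion coefficient by likelihood ratio (df = 1), BH-adjusting across
#' genes.
#'
#' @param counts a [count_matrix()].
#' @param design matching single-species [study_design()].
#' @param alpha FDR threshold recorded with the result (default 0.05).
#' @param min_total low-count filter threshold (default 10).
#' @param prior_df dispersion-shrinkage prior df (default 10).
#' @param adjust_site if `FALSE`, site contrasts are dropped from both models
#'   (libraries treated as independent) - only useful to demonstrate the
#'   miscalibration that the nested design exists to avoid.
#' @return A data.frame of class `de_result`: `gene_id`, `log_fc` (log2
#'   recent/ancient), `log_cpm`, `p_value`, `fdr`; `alpha` as attribute.
#' @export
run_8vs8 <- function(counts, design, alpha = 0.05, min_total = 10,
                     prior_df = 10, adjust_site = TRUE) {
  design <- design_species(design)
  f <- filter_low_counts(counts[, design$library_id, drop = FALSE], min_total)
  nf <- rle_factors(f)
  grp <- if (adjust_site) design$site else design$invasion_category
  common <- estimate_common_dispersion(f, nf, grp)
  disp <- estimate_tagwise_dispersions(f, nf, grp, common, prior_df)

  X_full <- nested_design_matrix(design, include_invasion = TRUE,
                                 include_site = adjust_site)
  X_red <- nested_design_matrix(design, include_invasion = FALSE,
                                include_site = adjust_site)
  offs <- log(nf$effective_lib_size)
  lcpm <- log_cpm(f, nf)
  G <- nrow(f)
  pv <- numeric(G); lfc <- numeric(G)
  y <- unclass(f)
  # reported log2 FCs come from a prior-count-augmented fit (average prior
  # 0.125 per library, scaled by relative library size) so that genes with an
  # empty category keep finite fold changes; the LRT uses the raw counts
  eff <- nf$effective_lib_size
  prior <- 0.125 * eff / mean(eff)
  offs_rep <- log(eff + 2 * prior)
  for (i in seq_len(G)) {
    full <- fit_nb_glm(y[i, ], X_full, offs, disp$shrunk[i])
    red <- fit_nb_glm(y[i, ], X_red, offs, disp$shrunk[i])
    pv[i] <- lr_test(full, red, df = 1L)
    rep_fit <- fit_nb_glm(y[i, ] + prior, X_full, offs_rep, disp$shrunk[i])
    lfc[i] <- rep_fit$coefficients[["recent"]] / log(2)
  }
  out <- data.frame(gene_id = rownames(f), log_fc = lfc,
                    log_cpm = rowMeans(lcpm), p_value = pv,
                    fdr = bh_adjust(pv), stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "dispersion") <- disp
  class(out) <- c("de_result", "data.frame")
  out
}

#' @keywords internal
#' Model matrix: intercept + invasion indicator (recent = 1) + sum-to-zero
#' site contrasts within each category (3 columns per category of 4 sites).
#' Together the 8 columns span the site-mean space.
nested_design_matrix <- function(design, include_invasion = TRUE,
                                 include_site = TRUE) {
  n <- nrow(design)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (include_invasion)
    X <- cbind(X, recent = as.numeric(design$invasion_category == "recent"))
  if (include_site) {
    for (cg in unique(design$invasion_category)) {
      sites <- unique(design$site[design$invasion_category == cg])
      ref <- sites[length(sites)]
      for (s in sites[-length(sites)]) {
        col <- (design$site == s) - (design$site == ref)
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- paste0("site_", s)
      }
    }
  }
  X
}

#' Run the shared-correlation random-effects analysis
#'
#' Filter, normalize, transform to log2-CPM, estimate the shared within-site
#' replicate correlation, and test the invasion contrast per gene with the
#' empirical-Bayes moderated GLS t-statistic, BH-adjusting across genes.
#'
#' @inheritParams run_8vs8
#' @param prior log-CPM prior count (default 0.5).
#' @return A `de_result` data.frame (as in [run_8vs8()]); the estimated
#'   consensus correlation is attached as attribute `"rho"` and reported via
#'   `message()`.
#' @export
run_ranef <- function(counts, design, alpha = 0.05, min_total = 10,
                      prior = 0.5) {
  design <- design_species(design)
  f <- filter_low_counts(counts[, design$library_id, drop = FALSE], min_total)
  nf <- rle_factors(f)
  lcpm <- log_cpm(f, nf, prior)
  rho <- estimate_duplicate_correlation(lcpm, design)
  fit <- gls_moderated_test(lcpm, design, rho)
  message(sprintf("shared within-site correlation estimate: %.4f", rho))
  out <- data.frame(gene_id = rownames(f),
                    log_fc = fit$coefficients[, "recent"],
                    log_cpm = rowMeans(lcpm),
                    p_value = fit$p_value,
                    fdr = bh_adjust(fit$p_value),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "rho") <- as.numeric(rho)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Combine the strategies into the consensus DE call
#'
#' A gene is consensus-DE (`final_de`) when it is significant in the 8vs8
#' analysis AND significant in at least `ceiling(threshold_frac * n_combos)`
#' of the 4vs4 replicate combinations (218 of 256 at the default 85%).
#' `systematic_4vs4` flags genes significant in every combination. Gene
#' universes are joined on their union, with explicit presence flags.
#'
#' @param tally a `combo_tally` from [run_4vs4_all()].
#' @param de_8vs8 a `de_result` from [run_8vs8()].
#' @param de_ranef optional `de_result` from [run_ranef()].
#' @param threshold_frac consensus fraction (default 0.85).
#' @param alpha FDR threshold applied to the 8vs8 and random-effects tables.
#' @return A data.frame of class `consensus_result` with one row per gene in
#'   the union universe: `gene_id`, `n_combos_de`, `n_combos_total`,
#'   `in_4vs4_universe`, `in_8vs8_universe`, `in_8vs8`, `in_ranef`,
#'   `systematic_4vs4`, `final_de`. Attributes: `consensus_threshold`,
#'   `threshold_frac`, `tally_histogram` (tally distribution of
#'   8vs8-significant genes, for threshold diagnosis).
#' @export
combine_calls <- function(tally, de_8vs8, de_ranef = NULL,
                          threshold_frac = 0.85, alpha = 0.05) {
  if (threshold_frac <= 0 || threshold_frac > 1)
    parameter_error("threshold_frac must lie in (0, 1]")
  n_tot <- tally$n_combos
  thr <- as.integer(ceiling(threshold_frac * n_tot))
  genes <- union(names(tally$tally), de_8vs8$gene_id)
  if (!is.null(de_ranef)) genes <- union(genes, de_ranef$gene_id)
  nc <- stats::setNames(integer(length(genes)), genes)
  nc[names(tally$tally)] <- tally$tally
  in8_universe <- genes %in% de_8vs8$gene_id
  in8 <- genes %in% de_8vs8$gene_id[de_8vs8$fdr < alpha]
  inr <- if (is.null(de_ranef)) rep(NA, length(genes))
  else genes %in% de_ranef$gene_id[de_ranef$fdr < alpha]
  out <- data.frame(
    gene_id = genes,
    n_combos_de = as.integer(nc),
    n_combos_total = n_tot,
    in_4vs4_universe = genes %in% names(tally$tally),
    in_8vs8_universe = in8_universe,
    in_8vs8 = in8,
    in_ranef = inr,
    systematic_4vs4 = as.integer(nc) == n_tot,
    final_de = in8 & as.integer(nc) >= thr,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  hist_tab <- table(factor(out$n_combos_de[out$in_8vs8], levels = 0:n_tot))
  attr(out, "consensus_threshold") <- thr
  attr(out, "threshold_frac") <- threshold_frac
  attr(out, "tally_histogram") <- data.frame(
    n_combos_de = 0:n_tot, n_genes = as.integer(hist_tab))
  class(out) <- c("consensus_result", "data.frame")
  out
}
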