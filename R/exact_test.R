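#' Negative-binomial conditional exact test for one gene
#'
#' The two-group test used in each 4vs4 replicate-selection run. Library
#' counts are first scaled to a common effective library size (the mean of the
#' effective sizes) as pseudo-counts, rounded half-to-even. Writing A and B for
#' the group pseudo-sums and T = A + B, the null distribution of A conditional
#' on T is the convolution of the groups' NB totals (sums of per-library NB
#' variables with common mean and dispersion); the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one
#' (minimum-likelihood convention, with a 1 + 1e-12 relative tolerance for
#' floating-point ties).
#'
#' @param group_a_counts integer counts for the gene in group A libraries
#'   (the reference category, e.g. ancient).
#' @param group_b_counts integer counts in group B libraries (e.g. recent).
#' @param factors a `norm_factors` table for the libraries in the order
#'   `c(a, b)`, or `NULL` for equal library sizes.
#' @param dispersion NB dispersion phi (var = mu + phi mu^2).
#' @return A list with `log_fc` (log2 of group B over group A abundance,
#'   positive when expression is higher in B), `p_value`, and `degenerate`
#'   (`TRUE` when the gene has zero pseudo-counts overall, in which case
#'   `p_value = 1` and `log_fc = 0`).
#' @export
nb_exact_test <- function(group_a_counts, group_b_counts, factors = NULL,
                          dispersion = 0.1) {
  na <- length(group_a_counts)
  nb <- length(group_b_counts)
  if (na == 0L || nb == 0L) domain_error("both groups must be non-empty")
  cc <- c(group_a_counts, group_b_counts)
  if (is.null(factors)) eff <- rep(1, na + nb)
  else eff <- factors$effective_lib_size
  pseudo <- round(cc * mean(eff) / eff)  # round() is half-to-even
  A <- sum(pseudo[seq_len(na)])
  B <- sum(pseudo[na + seq_len(nb)])
  lfc <- log2(((B + 0.5) / nb) / ((A + 0.5) / na))
  Tt <- A + B
  if (Tt == 0)
    return(list(log_fc = 0, p_value = 1, degenerate = TRUE))
  p <- exact_test_pvalue(A, Tt, na, nb, max(dispersion, 1e-10))
  list(log_fc = lfc, p_value = p, degenerate = FALSE)
}

#' @keywords internal
#' Conditional two-sided p-value for A successes of total Tt, group sizes
#' na/nb, dispersion phi. Support is restricted to a window of +/- 50
#' conditional standard deviations (always containing the observed value);
#' mass outside is far below double precision.
exact_test_pvalue <- function(A, Tt, na, nb, phi) {
  n <- na + nb
  lam <- Tt / n
  size_a <- na / phi
  size_b <- nb / phi
  # conditional moments: A | T is beta-binomial(T, na/phi, nb/phi)
  ab <- n / phi
  m <- Tt * na / n
  v <- Tt * (na / n) * (nb / n) * (ab + Tt) / (ab + 1)
  hw <- 50 * sqrt(max(v, 1))
  lo <- max(0, floor(min(m - hw, A - 5)))
  hi <- min(Tt, ceiling(max(m + hw, A + 5)))
  a <- lo:hi
  lp <- stats::dnbinom(a, size = size_a, mu = na * lam, log = TRUE) +
    stats::dnbinom(Tt - a, size = size_b, mu = nb * lam, log = TRUE)
  lmax <- max(lp)
  pr <- exp(lp - lmax)
  tot <- sum(pr)
  p_obs <- pr[A - lo + 1L]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]) / tot)
}

#' @keywords internal
#' Vectorized exact tests for all genes of a two-group count matrix.
#' counts: filtered count_matrix; group: factor/character with 2 levels, the
#' FIRST level is the reference (group A); eff: effective library sizes;
#' dispersion: scalar or per-gene vector.
exact_test_all <- function(counts, group, eff, dispersion) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) design_error("exact test needs exactly two groups")
  ja <- which(group == levels(group)[1L])
  jb <- which(group == levels(group)[2L])
  m <- unclass(counts)
  pseudo <- round(sweep(m, 2L, mean(eff) / eff, "*"))
  A <- .rowSums(pseudo[, ja, drop = FALSE], nrow(m), length(ja))
  B <- .rowSums(pseudo[, jb, drop = FALSE], nrow(m), length(jb))
  na <- length(ja); nb <- length(jb)
  phi <- rep_len(dispersion, nrow(m))
  pv <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    Tt <- A[i] + B[i]
    pv[i] <- if (Tt == 0) 1 else
      exact_test_pvalue(A[i], Tt, na, nb, max(phi[i], 1e-10))
  }
  data.frame(gene_id = rownames(m),
             log_fc = log2(((B + 0.5) / nb) / ((A + 0.5) / na)),
             p_value = pv,
             stringsAsFactors = FALSE)
}
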