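#' Shared within-site correlation of replicate pools
#'
#' Estimates the single correlation, shared across genes, between the two
#' replicate libraries of a site after removing invasion-category means.
#' Per gene the intra-site correlation of the residual replicate pairs is
#' computed as the one-way ANOVA intraclass correlation
#' `(MSB - MSW) / (MSB + MSW)` (MSB: mean square between sites within
#' categories; MSW: between replicates within sites), which is centred at the
#' true within-site correlation. Gene-level estimates are pooled on the
#' Fisher-z (atanh) scale with a 5%-trimmed mean; the result is transformed
#' back and clipped to (-0.99, 0.99).
#'
#' @param log_cpm numeric matrix of log2-CPM values (genes x libraries).
#' @param design a [study_design()] with exactly 2 replicate pools per site;
#'   column order of `log_cpm` must match the design rows.
#' @return The consensus correlation (scalar), with the per-gene estimates
#'   attached as attribute `"genewise"`.
#' @export
estimate_duplicate_correlation <- function(log_cpm, design) {
  design <- design_species(design)
  if (ncol(log_cpm) != nrow(design))
    design_error("log-CPM columns do not match design rows")
  reps <- table(design$site)
  if (any(reps != 2L))
    design_error("every site must have exactly 2 replicate libraries")
  sites <- unique(design$site)
  S <- length(sites)
  cats <- unique(design$invasion_category)

  e <- log_cpm
  for (cg in cats) {
    j <- which(design$invasion_category == cg)
    e[, j] <- e[, j] - rowMeans(log_cpm[, j, drop = FALSE])
  }
  i1 <- vapply(sites, function(s)
    which(design$site == s & design$pool_index == 1L), 1L)
  i2 <- vapply(sites, function(s)
    which(design$site == s & design$pool_index == 2L), 1L)
  m <- (e[, i1, drop = FALSE] + e[, i2, drop = FALSE]) / 2   # site means
  d <- (e[, i1, drop = FALSE] - e[, i2, drop = FALSE])
  msb <- 2 * rowSums(m^2) / (S - length(cats))
  msw <- rowSums(d^2 / 2) / S
  tot <- msb + msw
  ok <- tot > 0
  r <- (msb[ok] - msw[ok]) / tot[ok]
  r <- pmin(pmax(r, -0.9999), 0.9999)
  z <- atanh(r)
  rho <- tanh(mean(z, trim = 0.05))
  rho <- min(max(rho, -0.99), 0.99)
  rg <- rep(NA_real_, nrow(log_cpm)); rg[ok] <- r
  attr(rho, "genewise") <- rg
  rho
}

#' @keywords internal
#' Newton inversion of the trigamma function (for the scaled-F moment fit).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (it in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' @keywords internal
#' Moment-matching fit of a scaled-F distribution to sample variances s2 with
#' df residual degrees of freedom, on the log scale. Returns list(df_prior,
#' var_prior). df_prior = Inf when the observed spread of log s2 is no larger
#' than expected from a chi-square alone.
fit_f_dist <- function(s2, df) {
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2L) return(list(df_prior = Inf, var_prior = stats::median(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar <= 0) return(list(df_prior = Inf, var_prior = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, var_prior = s02)
}

#' Moderated invasion-category test under a shared replicate correlation
#'
#' Per gene, generalized least squares with block-diagonal covariance (2x2
#' blocks per site, off-diagonal `rho * sigma^2`) estimates the
#' invasion-category contrast from the log-CPM matrix; the pairs are whitened
#' analytically (scaled sum and difference of the two replicates). Residual
#' variances are shrunk by empirical Bayes: a scaled-F distribution is
#' moment-matched to the log residual variances, and the moderated t uses the
#' posterior variance `(d0 s0^2 + d s^2) / (d0 + d)` with `d0 + d` degrees of
#' freedom (two-sided p). With `rho = 0` and no shrinkage the statistic
#' reduces to the ordinary equal-variance two-sample t across libraries.
#'
#' @param log_cpm numeric matrix of log2-CPM values (genes x libraries).
#' @param design a [study_design()] with 2 replicate pools per site.
#' @param rho shared within-site correlation, typically from
#'   [estimate_duplicate_correlation()]; must satisfy `|rho| < 1`.
#' @param moderate logical; `FALSE` disables the empirical-Bayes step
#'   (ordinary GLS t with residual df).
#' @return A list of class `correlation_model_fit`: `consensus_correlation`,
#'   `coefficients` (genes x 2: intercept and recent-vs-ancient log2 FC),
#'   `residual_var`, `moderated_t`, `p_value`, `df_residual`, `df_total`,
#'   `prior_df_eb`, `prior_var_eb`.
#' @export
gls_moderated_test <- function(log_cpm, design, rho, moderate = TRUE) {
  if (!is.finite(rho) || abs(rho) >= 1)
    domain_error("|rho| must be < 1 for a positive-definite covariance")
  design <- design_species(design)
  if (any(table(design$site) != 2L))
    design_error("every site must have exactly 2 replicate libraries")
  sites <- unique(design$site)
  i1 <- vapply(sites, function(s)
    which(design$site == s & design$pool_index == 1L), 1L)
  i2 <- vapply(sites, function(s)
    which(design$site == s & design$pool_index == 2L), 1L)
  x <- as.numeric(design$invasion_category == "recent")
  X <- cbind(intercept = 1, recent = x)

  a_s <- 1 / sqrt(2 * (1 + rho))   # weight for the within-pair sum
  a_d <- 1 / sqrt(2 * (1 - rho))   # weight for the within-pair difference
  Yw <- rbind(t(log_cpm[, i1, drop = FALSE] + log_cpm[, i2, drop = FALSE]) * a_s,
              t(log_cpm[, i1, drop = FALSE] - log_cpm[, i2, drop = FALSE]) * a_d)
  Xw <- rbind((X[i1, ] + X[i2, ]) * a_s,
              (X[i1, ] - X[i2, ]) * a_d)

  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) design_error("rank-deficient whitened design")
  beta <- t(qr.coef(qx, Yw))
  res <- qr.resid(qx, Yw)
  n <- nrow(design)
  d <- n - ncol(Xw)
  s2 <- colSums(res^2) / d
  xtxinv <- chol2inv(qr.R(qx))
  u <- xtxinv[2L, 2L]

  if (moderate) {
    fd <- fit_f_dist(s2, rep(d, length(s2)))
    d0 <- fd$df_prior; s02 <- fd$var_prior
  } else {
    d0 <- 0; s02 <- 0
  }
  post_var <- if (is.infinite(d0)) rep(s02, length(s2))
  else (d0 * s02 + d * s2) / (d0 + d)
  tt <- beta[, 2L] / sqrt(post_var * u)
  df_tot <- d0 + d
  pv <- 2 * stats::pt(-abs(tt), df = df_tot)
  out <- list(consensus_correlation = as.numeric(rho),
              coefficients = beta,
              residual_var = s2,
              moderated_t = tt,
              p_value = pv,
              df_residual = d,
              df_total = df_tot,
              prior_df_eb = d0,
              prior_var_eb = s02)
  class(out) <- "correlation_model_fit"
  out
}
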