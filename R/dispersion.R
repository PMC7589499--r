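#' @keywords internal
#' Adjusted profile log-likelihood of the NB model at dispersion phi.
#'
#' For each gene and each group of libraries, the group mean parameter is
#' profiled out: mu_gj = q_{g,group(j)} * eff_j with q maximizing the NB
#' likelihood at the given phi, solved by Fisher scoring on log q and
#' vectorized over genes (score sum (y - mu)/(1 + phi mu), information
#' sum mu/(1 + phi mu)). With `adjust = TRUE` (the default) the Cox-Reid
#' adjustment -0.5 log det(X'WX) is applied per profiled group mean
#' (W = diag(mu/(1+phi mu))), which removes the downward bias that plain
#' profiling incurs from estimating one nuisance mean per group.
#'
#' y: genes x libraries matrix; eff: effective library sizes; groups: factor.
#' Returns list(loglik = per-gene (adjusted) profile log-likelihood,
#' mu = fitted means).
nb_profile_loglik <- function(y, eff, groups, phi, adjust = TRUE) {
  y <- unclass(y)
  G <- nrow(y)
  mu <- matrix(0, G, ncol(y))
  adj <- numeric(G)
  groups <- as.factor(groups)
  for (g in levels(groups)) {
    j <- which(groups == g)
    yg <- y[, j, drop = FALSE]
    eg <- eff[j]
    tot <- .rowSums(yg, G, length(j))
    q <- tot / sum(eg)
    nz <- which(tot > 0)
    if (length(nz)) {
      lq <- log(q[nz])
      yn <- yg[nz, , drop = FALSE]
      for (it in 1:30) {
        mug <- exp(lq) %o% eg
        w <- 1 + phi * mug
        step <- .rowSums((yn - mug) / w, length(nz), length(j)) /
          pmax(.rowSums(mug / w, length(nz), length(j)), 1e-300)
        step <- pmax(pmin(step, 3), -3)
        lq <- lq + step
        if (max(abs(step)) < 1e-10) break
      }
      q[nz] <- exp(lq)
      if (adjust) {
        mug <- exp(lq) %o% eg
        info <- .rowSums(mug / (1 + phi * mug), length(nz), length(j))
        adj[nz] <- adj[nz] - 0.5 * log(pmax(info, 1e-300))
      }
    }
    mu[, j] <- q %o% eg
  }
  ll <- .rowSums(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE),
                 G, ncol(y)) + adj
  list(loglik = ll, mu = mu)
}

#' Common negative-binomial dispersion
#'
#' Maximizes the sum over genes of the per-gene NB adjusted profile
#' log-likelihood (group means profiled out at each candidate dispersion,
#' with the Cox-Reid adjustment for the profiled means) over `phi` in
#' `[1e-8, 10]`, by golden-section search on log(phi) to tolerance 1e-6.
#' `design` gives the group label of each library (invasion category for a
#' 4vs4 subset; site for the full nested design, whose 8-column model matrix
#' spans exactly the site-mean space).
#'
#' @param counts a filtered [count_matrix()].
#' @param factors a `norm_factors` table for the same libraries.
#' @param design vector of group labels, one per library.
#' @param adjust apply the Cox-Reid adjustment (default `TRUE`).
#' @return The common dispersion (positive scalar).
#' @export
estimate_common_dispersion <- function(counts, factors, design, adjust = TRUE) {
  if (ncol(counts) < 2L) design_error("dispersion estimation needs >= 2 libraries")
  eff <- factors$effective_lib_size
  bounds <- log(c(1e-8, 10))
  obj <- function(lphi) {
    v <- sum(nb_profile_loglik(counts, eff, design, exp(lphi), adjust)$loglik)
    if (!is.finite(v)) numeric_error("non-finite likelihood in dispersion search")
    v
  }
  opt <- stats::optimize(obj, interval = bounds, maximum = TRUE, tol = 1e-6)
  lphi <- opt$maximum
  # snap to a bound when the optimum sits against it
  if (lphi - bounds[1] < 1e-3 && obj(bounds[1] + 1e-9) >= opt$objective - 1e-9)
    lphi <- bounds[1]
  if (bounds[2] - lphi < 1e-3 && obj(bounds[2] - 1e-9) >= opt$objective - 1e-9)
    lphi <- bounds[2]
  exp(lphi)
}

#' Gene-wise dispersions with weighted-likelihood shrinkage
#'
#' Per-gene dispersions maximizing the gene's adjusted profile log-likelihood
#' plus a shared penalty `(prior_df / residual_df) * mean-gene
#' log-likelihood`, i.e. weighted-likelihood shrinkage toward the common
#' value; the estimate moves monotonically from the per-gene MLE to the
#' common dispersion as `prior_df` grows. `prior_df = 0` gives the
#' unpenalized per-gene MLE; `prior_df = Inf` (or any huge value) returns the
#' common dispersion for every gene.
#'
#' Optimization evaluates the likelihoods on a log-spaced dispersion grid
#' densified around the common value and refines each gene's maximum with a
#' quadratic (parabolic) interpolation of the three bracketing grid points;
#' all genes are processed in vectorized sweeps.
#'
#' @param counts a filtered [count_matrix()].
#' @param factors a `norm_factors` table.
#' @param design vector of group labels, one per library.
#' @param common common dispersion from [estimate_common_dispersion()].
#' @param prior_df prior degrees of freedom controlling shrinkage (default 10).
#' @param adjust apply the Cox-Reid adjustment (default `TRUE`).
#' @return A list of class `dispersion_estimates` with elements `common`,
#'   `genewise`, `shrunk` (named per gene), and `prior_df`.
#' @export
estimate_tagwise_dispersions <- function(counts, factors, design, common,
                                         prior_df = 10, adjust = TRUE) {
  eff <- factors$effective_lib_size
  G <- nrow(counts)
  n <- ncol(counts)
  groups <- as.factor(design)
  df_res <- n - nlevels(groups)
  wrap <- function(genewise, shrunk) {
    names(genewise) <- names(shrunk) <- rownames(counts)
    out <- list(common = common, genewise = genewise, shrunk = shrunk,
                prior_df = prior_df)
    class(out) <- "dispersion_estimates"
    out
  }
  if (df_res <= 0 || !is.finite(prior_df) || prior_df >= 1e8)
    return(wrap(rep(common, G), rep(common, G)))
  w <- prior_df / df_res

  bounds <- log(c(1e-8, 10))
  lgrid <- sort(unique(c(
    seq(bounds[1], bounds[2], length.out = 21),
    seq(max(bounds[1], log(common) - 5), min(bounds[2], log(common) + 5),
        length.out = 64),
    log(common))))
  LL <- vapply(lgrid, function(l)
    nb_profile_loglik(counts, eff, groups, exp(l), adjust)$loglik,
    numeric(G))
  if (G == 1L) LL <- matrix(LL, nrow = 1L)
  llcom <- colMeans(LL)

  argmax_refined <- function(M) {
    # per-row grid argmax + parabolic refinement on log-dispersion
    j <- max.col(M, ties.method = "first")
    j <- pmin(pmax(j, 2L), length(lgrid) - 1L)
    idx <- cbind(seq_len(nrow(M)), j)
    y0 <- M[cbind(idx[, 1], j - 1L)]
    y1 <- M[idx]
    y2 <- M[cbind(idx[, 1], j + 1L)]
    x0 <- lgrid[j - 1L]; x1 <- lgrid[j]; x2 <- lgrid[j + 1L]
    denom <- (y0 - y1) * (x1 - x2) - (y1 - y2) * (x0 - x1)
    vertex <- ifelse(abs(denom) > 1e-12,
                     ((y0 - y1) * (x1^2 - x2^2) - (y1 - y2) * (x0^2 - x1^2)) /
                       (2 * denom), x1)
    ifelse(is.finite(vertex) & vertex >= x0 & vertex <= x2, vertex, x1)
  }

  genewise <- pmin(pmax(exp(argmax_refined(LL)), 1e-8), 10)
  shrunk <- if (w == 0) genewise
  else pmin(pmax(exp(argmax_refined(LL + w * rep(llcom, each = G))), 1e-8), 10)
  wrap(genewise, shrunk)
}
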