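# Shared fixture builders. Everything is generated in code; no data files.

# Minimal single-species design: S sites per category, 2 pools each.
toy_design <- function(n_sites_per_category = 4, species = "mouse") {
  sites <- c(paste0("A", seq_len(n_sites_per_category)),
             paste0("R", seq_len(n_sites_per_category)))
  cats <- rep(c("ancient", "recent"), each = n_sites_per_category)
  n <- 2L * length(sites)
  study_design(data.frame(
    library_id = paste0(species, "_", rep(sites, each = 2), "_P", 1:2),
    species = species,
    site = rep(sites, each = 2),
    invasion_category = rep(cats, each = 2),
    pool_index = rep(1:2, length(sites)),
    pool_size = rep(8L, n),
    n_males = rep(4L, n),
    n_females = rep(4L, n),
    stringsAsFactors = FALSE))
}

# Random count matrix with all-positive rows guaranteed (for RLE).
random_counts <- function(G, n, seed, mu = 60, phi = 0.1) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(G * n, size = 1 / phi, mu = mu) + 1, G, n)
  count_matrix(m, sprintf("g%04d", seq_len(G)), sprintf("lib%02d", seq_len(n)))
}

# Gaussian log-expression matrix with exact within-site correlation rho,
# columns ordered to match toy_design(4) (pairs adjacent).
gaussian_block_matrix <- function(G, design, rho, seed) {
  set.seed(seed)
  S <- length(unique(design$site))
  u <- matrix(stats::rnorm(G * S, 0, sqrt(rho)), G, S)
  e1 <- u + matrix(stats::rnorm(G * S, 0, sqrt(1 - rho)), G, S)
  e2 <- u + matrix(stats::rnorm(G * S, 0, sqrt(1 - rho)), G, S)
  x <- matrix(0, G, 2 * S)
  x[, seq(1, 2 * S, 2)] <- e1
  x[, seq(2, 2 * S, 2)] <- e2
  colnames(x) <- design$library_id
  rownames(x) <- sprintf("g%04d", seq_len(G))
  x
}

# Independent oracle: brute-force conditional exact test by full enumeration
# of a = 0..T with NB convolution probabilities (no windowing, no shortcuts).
brute_exact_p <- function(A, Tt, na, nb, phi) {
  a <- 0:Tt
  lam <- Tt / (na + nb)
  lp <- stats::dnbinom(a, size = na / phi, mu = na * lam, log = TRUE) +
    stats::dnbinom(Tt - a, size = nb / phi, mu = nb * lam, log = TRUE)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[A + 1] * (1 + 1e-12)])
}

# Independent oracle: BH step-up straight from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# Independent oracle: hypergeometric upper tail by pmf summation.
brute_hyper_upper <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}
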