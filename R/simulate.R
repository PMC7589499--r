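#' Simulation configuration for the nested pooled-replicate design
#'
#' Defines the study conditions the generator emulates: two invasion
#' categories, `n_sites_per_category` sites each, `n_pools_per_site` pooled
#' replicate libraries per site (pools of 6-10 individuals with balanced sex
#' ratio), NB-distributed counts with gene-specific site-level random effects
#' on the log2 scale and a planted invasion-category effect for a subset of
#' genes, including an "immune"-labelled subset whose true log fold changes
#' are shifted upward.
#'
#' @param n_genes number of genes.
#' @param n_sites_per_category sites per invasion category (default 4).
#' @param n_pools_per_site replicate pools per site (default 2).
#' @param frac_de fraction of genes with a true invasion effect.
#' @param lfc_magnitude mean |log2 FC| of true effects; magnitudes are drawn
#'   `|Normal(lfc_magnitude, lfc_magnitude/4)|` with random sign.
#' @param site_sd SD of per-gene per-site log2-scale random effects.
#' @param dispersion_location,dispersion_sd log-normal parameters (meanlog,
#'   sdlog) of the gene-wise NB dispersion.
#' @param baseline_location,baseline_sd log-normal parameters of the per-gene
#'   baseline expected count per unit library factor.
#' @param libsize_location,libsize_sd log-normal parameters of the per-library
#'   size factor.
#' @param frac_immune fraction of genes labelled "immune".
#' @param immune_lfc_shift additive log2-FC shift applied to DE immune genes.
#' @param shared_site_effects if `TRUE`, one site effect shared by all genes
#'   (instead of gene-specific, the default).
#' @param species species label written into the design.
#' @param seed integer seed; all randomness flows from it via per-stage
#'   derived streams, so identical seeds give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_sites_per_category = 4,
                       n_pools_per_site = 2,
                       frac_de = 0.05,
                       lfc_magnitude = 2,
                       site_sd = 0.25,
                       dispersion_location = log(0.1),
                       dispersion_sd = 0.5,
                       baseline_location = log(50),
                       baseline_sd = 1.2,
                       libsize_location = 0,
                       libsize_sd = 0.2,
                       frac_immune = 0.1,
                       immune_lfc_shift = 1,
                       shared_site_effects = FALSE,
                       species = "mouse",
                       seed = 1) {
  cfg <- as.list(environment())
  if (n_genes < 1) parameter_error("n_genes must be >= 1")
  for (f in c("frac_de", "frac_immune"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      parameter_error(sprintf("%s must lie in [0, 1]", f))
  for (s in c("site_sd", "dispersion_sd", "baseline_sd", "libsize_sd"))
    if (cfg[[s]] < 0) parameter_error(sprintf("%s must be >= 0", s))
  if (lfc_magnitude < 0) parameter_error("lfc_magnitude must be >= 0")
  if (n_sites_per_category < 1 || n_pools_per_site < 1)
    parameter_error("need >= 1 site per category and >= 1 pool per site")
  cfg$n_genes <- as.integer(n_genes)
  cfg$n_sites_per_category <- as.integer(n_sites_per_category)
  cfg$n_pools_per_site <- as.integer(n_pools_per_site)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Per-stage seed derived from the single user seed; keeps every stage on its
# own reproducible stream and all values below 2^31.
stage_seed <- function(seed, stage) {
  ((as.double(seed) %% 65011) * 33013 + stage * 7919) %% 2147483647
}

#' Simulate a count matrix, design and ground truth
#'
#' Counts follow `c_gj ~ NB(mean = s_j q_g 2^(x_j beta_g + u_{g,site(j)}),
#' dispersion phi_g)` with `x_j = 1` for recently invaded sites and 0 for
#' anciently invaded ones; `s_j` and `q_g` are log-normal library and baseline
#' factors, `u` are Normal(0, site_sd^2) site effects, and `beta_g` is the
#' true signed log2 fold change (zero for non-DE genes). Pool sizes are drawn
#' uniformly from 6-10 individuals with `n_males = floor(pool_size/2)` or the
#' ceiling, alternating across libraries. Identical seeds give bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return A list with elements `counts` ([count_matrix()]), `design`
#'   ([study_design()]), and `truth` (list with per-gene data.frame `genes`
#'   holding `gene_id`, `true_lfc`, `is_de`, `is_immune`, `true_dispersion`;
#'   matrix `site_effects` (genes x sites); `terms = NULL` until
#'   [simulate_annotation()] is run).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  G <- config$n_genes
  S <- 2L * config$n_sites_per_category
  P <- config$n_pools_per_site
  nlib <- S * P

  sites <- c(paste0("A", seq_len(config$n_sites_per_category)),
             paste0("R", seq_len(config$n_sites_per_category)))
  cat_of_site <- rep(c("ancient", "recent"), each = config$n_sites_per_category)

  # design metadata (pool sizes 6-10, balanced sex ratio)
  set.seed(stage_seed(config$seed, 1))
  pool_size <- sample(6:10, nlib, replace = TRUE)
  lib_site <- rep(sites, each = P)
  lib_cat <- rep(cat_of_site, each = P)
  n_males <- ifelse(seq_len(nlib) %% 2L == 1L,
                    floor(pool_size / 2), ceiling(pool_size / 2))
  design <- study_design(data.frame(
    library_id = paste0(config$species, "_", lib_site, "_P", rep(seq_len(P), S)),
    species = config$species,
    site = lib_site,
    invasion_category = lib_cat,
    pool_index = rep(seq_len(P), S),
    pool_size = pool_size,
    n_males = n_males,
    n_females = pool_size - n_males,
    stringsAsFactors = FALSE))

  # gene-level truth
  set.seed(stage_seed(config$seed, 2))
  gid <- sprintf("g%05d", seq_len(G))
  n_de <- round(config$frac_de * G)
  is_de <- logical(G)
  if (n_de > 0) is_de[sample.int(G, n_de)] <- TRUE
  n_imm <- round(config$frac_immune * G)
  is_immune <- logical(G)
  if (n_imm > 0) is_immune[sample.int(G, n_imm)] <- TRUE
  beta <- numeric(G)
  if (n_de > 0) {
    mag <- abs(stats::rnorm(n_de, config$lfc_magnitude, config$lfc_magnitude / 4))
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    beta[is_de] <- sgn * mag
    beta[is_de & is_immune] <- beta[is_de & is_immune] + config$immune_lfc_shift
  }
  phi <- pmin(pmax(stats::rlnorm(G, config$dispersion_location,
                                 config$dispersion_sd), 1e-6), 10)
  q <- stats::rlnorm(G, config$baseline_location, config$baseline_sd)

  # site effects
  set.seed(stage_seed(config$seed, 3))
  u <- if (config$shared_site_effects)
    matrix(stats::rnorm(S, 0, config$site_sd), G, S, byrow = TRUE)
  else matrix(stats::rnorm(G * S, 0, config$site_sd), G, S)
  colnames(u) <- sites

  # counts
  set.seed(stage_seed(config$seed, 4))
  s_lib <- stats::rlnorm(nlib, config$libsize_location, config$libsize_sd)
  x <- as.numeric(lib_cat == "recent")
  site_idx <- match(lib_site, sites)
  counts <- matrix(0, G, nlib)
  for (j in seq_len(nlib)) {
    mu <- s_lib[j] * q * 2^(x[j] * beta + u[, site_idx[j]])
    counts[, j] <- stats::rnbinom(G, size = 1 / phi, mu = mu)
  }
  cm <- count_matrix(counts, gene_ids = gid, library_ids = design$library_id)

  truth <- list(
    genes = data.frame(gene_id = gid, true_lfc = beta, is_de = is_de,
                       is_immune = is_immune, true_dispersion = phi,
                       stringsAsFactors = FALSE),
    site_effects = u,
    terms = NULL)
  list(counts = cm, design = design, truth = truth)
}

#' Simulate a gene-set annotation with planted enriched terms
#'
#' Term sizes are uniform in `term_size_range`. The first `n_enriched_terms`
#' terms sample genes with the odds of each truly DE gene multiplied by
#' `enrichment_odds`; the remaining terms sample genes uniformly.
#'
#' @param truth the `truth` element of [simulate_dataset()] output.
#' @param n_terms number of terms.
#' @param term_size_range integer pair, inclusive bounds on term size.
#' @param n_enriched_terms number of enriched terms (`<= n_terms`).
#' @param enrichment_odds odds multiplier for DE genes in enriched terms
#'   (1 = no enrichment).
#' @param seed integer seed.
#' @return A list with `annotation` (a `gene_set_collection`) and `truth`
#'   (input truth with a per-term data.frame `terms` added).
#' @export
simulate_annotation <- function(truth, n_terms = 100,
                                term_size_range = c(20, 80),
                                n_enriched_terms = 5,
                                enrichment_odds = 10,
                                seed = 1) {
  if (n_enriched_terms > n_terms)
    parameter_error("n_enriched_terms must be <= n_terms")
  if (enrichment_odds <= 0)
    parameter_error("enrichment_odds must be positive")
  genes <- truth$genes$gene_id
  G <- length(genes)
  if (max(term_size_range) > G)
    parameter_error("term_size_range exceeds the number of genes")
  set.seed(stage_seed(seed, 5))
  size_pool <- seq(term_size_range[1], term_size_range[2])
  sizes <- size_pool[sample.int(length(size_pool), n_terms, replace = TRUE)]
  w_enriched <- ifelse(truth$genes$is_de, enrichment_odds, 1)
  sets <- vector("list", n_terms)
  ids <- sprintf("T%04d", seq_len(n_terms))
  for (i in seq_len(n_terms)) {
    w <- if (i <= n_enriched_terms) w_enriched else rep(1, G)
    sets[[i]] <- list(description = if (i <= n_enriched_terms)
      "planted enriched term" else "background term",
      genes = genes[sample.int(G, sizes[i], prob = w)])
  }
  names(sets) <- ids
  class(sets) <- "gene_set_collection"
  truth$terms <- data.frame(term_id = ids,
                            is_enriched = seq_len(n_terms) <= n_enriched_terms,
                            stringsAsFactors = FALSE)
  list(annotation = sets, truth = truth)
}
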