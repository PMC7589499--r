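test_that("simulator reproduces the nested 16-library design and is deterministic", {
  sim <- simulate_dataset(sim_config(n_genes = 100, seed = 3))
  expect_equal(nrow(sim$design), 16L)
  expect_equal(length(unique(sim$design$site)), 8L)
  expect_equal(sum(sim$design$invasion_category == "recent"), 8L)
  expect_true(all(sim$design$pool_size %in% 6:10))
  expect_true(all(abs(sim$design$n_males - sim$design$n_females) <= 1L))
  expect_equal(ncol(sim$counts), 16L)
  expect_equal(nrow(sim$counts), 100L)

  # identical seed => bit-identical counts; different seed => different
  sim2 <- simulate_dataset(sim_config(n_genes = 100, seed = 3))
  expect_identical(unclass(sim$counts), unclass(sim2$counts))
  sim3 <- simulate_dataset(sim_config(n_genes = 100, seed = 4))
  expect_false(identical(unclass(sim$counts), unclass(sim3$counts)))

  # no planted effects => flat truth
  null_sim <- simulate_dataset(sim_config(n_genes = 50, frac_de = 0,
                                          site_sd = 0, seed = 1))
  expect_true(all(null_sim$truth$genes$true_lfc == 0))
  expect_true(all(null_sim$truth$site_effects == 0))

  # invalid configurations are rejected
  expect_error(sim_config(frac_de = 1.5), class = "comboDE_parameter_error")
  expect_error(sim_config(site_sd = -1), class = "comboDE_parameter_error")
  expect_error(sim_config(n_genes = 0), class = "comboDE_parameter_error")
})

test_that("counts follow the NB mean-variance relation var = mu + phi mu^2", {
  # 200 libraries (50 sites/category), 3 dispersions, no extra structure
  for (phi in c(0.05, 0.2, 1)) {
    sim <- simulate_dataset(sim_config(
      n_genes = 3, n_sites_per_category = 50, frac_de = 0, site_sd = 0,
      libsize_sd = 0, baseline_sd = 0, baseline_location = log(100),
      dispersion_location = log(phi), dispersion_sd = 0, seed = 17))
    m <- rowMeans(sim$counts)
    v <- apply(sim$counts, 1, stats::var)
    expected <- m + phi * m^2
    # 200 libraries: per-gene variance ratios within broad sampling error,
    # and centred on 1 across genes
    expect_true(all(v / expected > 0.55 & v / expected < 1.9))
    expect_equal(mean(v / expected), 1, tolerance = 0.25)
  }
})

test_that("annotation simulator plants detectable enrichment structure", {
  sim <- simulate_dataset(sim_config(n_genes = 1000, frac_de = 0.05, seed = 5))
  ann <- simulate_annotation(sim$truth, n_terms = 20,
                             term_size_range = c(50, 50),
                             n_enriched_terms = 5, enrichment_odds = 20,
                             seed = 5)
  expect_length(ann$annotation, 20L)
  expect_true(all(vapply(ann$annotation, function(s) length(s$genes), 1L) == 50L))
  expect_equal(sum(ann$truth$terms$is_enriched), 5L)

  # with odds = 1 all terms are exchangeable uniform draws; with odds = 20 the
  # enriched terms systematically overlap the DE set (Monte Carlo, 200 reps)
  de <- sim$truth$genes$gene_id[sim$truth$genes$is_de]
  overlap_gap <- vapply(1:200, function(r) {
    a <- simulate_annotation(sim$truth, n_terms = 4, term_size_range = c(50, 50),
                             n_enriched_terms = 2, enrichment_odds = 20,
                             seed = 1000 + r)$annotation
    ov <- vapply(a, function(s) length(intersect(s$genes, de)), 1L)
    mean(ov[1:2]) - mean(ov[3:4])
  }, 1)
  expect_gt(mean(overlap_gap), 0)
  expect_gt(mean(overlap_gap), 2)  # planted terms clearly separated on average

  # parameter validation
  expect_error(simulate_annotation(sim$truth, n_terms = 2, n_enriched_terms = 3),
               class = "comboDE_parameter_error")
  expect_error(simulate_annotation(sim$truth, term_size_range = c(10, 2000)),
               class = "comboDE_parameter_error")
  # single term covering every gene
  all_in <- simulate_annotation(sim$truth, n_terms = 1,
                                term_size_range = c(1000, 1000),
                                n_enriched_terms = 0, seed = 2)
  expect_setequal(all_in$annotation[[1]]$genes, sim$truth$genes$gene_id)
})
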