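mk_gsc <- function(...) {
  sets <- list(...)
  class(sets) <- "gene_set_collection"
  sets
}

test_that("hypergeometric enrichment closed forms and margins", {
  genes <- sprintf("g%02d", 1:20)
  ann <- mk_gsc(T1 = list(description = "d", genes = genes[1:5]))
  # N=20, K=5, n=5, k=5: p = 1/C(20,5)
  res <- fisher_enrichment(genes[1:5], genes, ann)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5L); expect_equal(res$K, 5L)
  expect_equal(res$n, 5L); expect_equal(res$N, 20L)
  expect_equal(res$direction, "over")

  # k = 0 with small K: upper tail includes nearly all mass
  res0 <- fisher_enrichment(genes[6:10], genes,
                            mk_gsc(T1 = list(description = "d",
                                             genes = genes[1:2])))
  expect_gt(res0$p_value, 0.5)
  expect_equal(res0$k, 0L)

  # DE genes outside the background are refused
  expect_error(fisher_enrichment(c("zz"), genes, ann),
               class = "comboDE_input_error")
  # terms without background genes are skipped
  resx <- fisher_enrichment(genes[1:3], genes,
                            mk_gsc(T1 = list(description = "d", genes = "zz")))
  expect_equal(nrow(resx), 0L)
})

test_that("hypergeometric p matches pmf summation on 500 random margins", {
  set.seed(81)
  universe <- sprintf("u%04d", 1:400)
  for (r in 1:500) {
    N <- sample(20:400, 1)
    bg <- universe[seq_len(N)]
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term <- sample(bg, K)
    de <- sample(bg, n)
    res <- fisher_enrichment(de, bg, mk_gsc(T = list(description = "", genes = term)))
    k <- length(intersect(term, de))
    expect_equal(res$p_value, brute_hyper_upper(k, N, K, n), tolerance = 1e-10)
  }
})

test_that("the 2x2 table is symmetric in which margin is called the gene set", {
  set.seed(82)
  bg <- sprintf("u%03d", 1:100)
  de <- sample(bg, 30)
  term <- sample(bg, 12)
  p1 <- fisher_enrichment(de, bg, mk_gsc(T = list(description = "", genes = term)))$p_value
  p2 <- fisher_enrichment(term, bg, mk_gsc(T = list(description = "", genes = de)))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("enrichment detection is powered on planted terms and calibrated on null terms", {
  # fixed truth; 200 annotation replicates with a planted odds-20 term
  sim <- simulate_dataset(sim_config(n_genes = 5000, frac_de = 0.05, seed = 83))
  de <- sim$truth$genes$gene_id[sim$truth$genes$is_de]
  bg <- sim$truth$genes$gene_id
  hits_planted <- logical(200)
  null_rate <- numeric(200)
  for (r in 1:200) {
    ann <- simulate_annotation(sim$truth, n_terms = 20,
                               term_size_range = c(50, 50),
                               n_enriched_terms = 1, enrichment_odds = 20,
                               seed = 9000 + r)$annotation
    res <- fisher_enrichment(de, bg, ann)
    sig <- res$term_id[res$fdr < 0.05]
    hits_planted[r] <- "T0001" %in% sig
    null_rate[r] <- mean(setdiff(res$term_id, "T0001") %in% sig)
  }
  expect_gte(mean(hits_planted), 0.9)
  expect_lte(mean(null_rate), 0.05)
})

test_that("Wilcoxon shift test modes match enumeration and approximation contracts", {
  # identical samples: approximate p = 1
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_shift_test(x, x, mode = "normal-approx"), 1)
  # exact enumeration: x=(1,2), y=(3,4) -> 2/6
  expect_equal(wilcoxon_shift_test(c(1, 2), c(3, 4), mode = "exact"),
               1 / 3, tolerance = 1e-12)
  expect_error(wilcoxon_shift_test(numeric(0), x),
               class = "comboDE_domain_error")
  expect_error(wilcoxon_shift_test(c(1, 1, 2), c(2, 3), mode = "exact"),
               class = "comboDE_domain_error")

  # normal approximation within 10% relative error of the exact enumeration
  # for tie-free null samples of 10 per group; the guarantee concerns the
  # body of the distribution, so far-tail draws (exact p < 0.05) are redrawn
  set.seed(84)
  checked <- 0L
  while (checked < 25L) {
    a <- stats::rnorm(10)
    b <- stats::rnorm(10)
    pe <- wilcoxon_shift_test(a, b, mode = "exact")
    if (pe < 0.05) next
    pn <- wilcoxon_shift_test(a, b, mode = "normal-approx")
    expect_lt(abs(pn - pe) / pe, 0.10)
    checked <- checked + 1L
  }
})

test_that("LFC shift comparison detects a planted immune shift and handles edges", {
  de_tab <- data.frame(gene_id = sprintf("g%03d", 1:300),
                       log_fc = c(stats::rnorm(100, 1), stats::rnorm(200, 0)))
  lab <- de_tab$gene_id[1:100]
  res <- compare_lfc_distributions(de_tab, lab)
  expect_equal(res$shift_direction, "higher")
  expect_lt(res$p_value, 0.01)

  # |LFC| comparison is invariant to a global sign flip
  flipped <- de_tab; flipped$log_fc <- -flipped$log_fc
  r1 <- compare_lfc_distributions(de_tab, lab, use_abs = TRUE)
  r2 <- compare_lfc_distributions(flipped, lab, use_abs = TRUE)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  # labels covering every gene leave no complement
  expect_error(compare_lfc_distributions(de_tab, de_tab$gene_id),
               class = "comboDE_domain_error")
})

test_that("a simulated immune LFC shift of 1 is detected from DE-gene estimates", {
  cfg <- sim_config(n_genes = 4000, frac_de = 0.1, lfc_magnitude = 2,
                    frac_immune = 0.25, immune_lfc_shift = 1, seed = 85)
  sim <- simulate_dataset(cfg)
  de8 <- run_8vs8(sim$counts, sim$design)
  tr <- sim$truth$genes
  de_genes <- intersect(de8$gene_id[de8$fdr < 0.05],
                        tr$gene_id[tr$is_de])
  tab <- de8[de8$gene_id %in% de_genes, ]
  expect_gte(nrow(tab), 200)
  res <- compare_lfc_distributions(tab, tr$gene_id[tr$is_immune])
  expect_equal(res$shift_direction, "higher")
  expect_lt(res$p_value, 0.01)
})
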