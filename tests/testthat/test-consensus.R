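test_that("combination enumeration is exhaustive, ordered and validated", {
  d <- toy_design(4)
  combos <- enumerate_combinations(d)
  expect_length(combos, 256L)
  expect_equal(length(unique(vapply(combos, paste, "", collapse = "|"))), 256L)
  # first combination: all pool-1 libraries; last: all pool-2
  expect_true(all(grepl("_P1$", combos[[1]])))
  expect_true(all(grepl("_P2$", combos[[256]])))
  # lexicographic: second combination flips only the last site
  expect_equal(sum(combos[[1]] != combos[[2]]), 1L)
  expect_true(grepl("_P2$", combos[[2]][8]))

  # product oracle for S in 2..5
  for (S in 2:5) {
    dS <- toy_design(S)  # 2S sites total
    expect_length(enumerate_combinations(dS), 2^(2 * S))
  }
  d1 <- study_design(as.data.frame(toy_design(1)))
  expect_length(enumerate_combinations(d1), 4L)  # 2 sites x 2 pools

  # a site with a missing replicate is refused
  bad <- as.data.frame(d)[-2, ]
  expect_error(enumerate_combinations(study_design(bad)),
               class = "comboDE_design_error")
})

test_that("consensus threshold arithmetic follows the more-than-85% rule", {
  mk_tally <- function(tallies, n_combos) {
    structure(list(tally = tallies, n_combos = n_combos,
                   per_combo_n_de = integer(n_combos), alpha = 0.05),
              class = "combo_tally")
  }
  mk_de <- function(genes, fdr) {
    structure(data.frame(gene_id = genes, log_fc = 0, log_cpm = 5,
                         p_value = fdr, fdr = fdr, stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  tally <- mk_tally(c(gA = 220L, gB = 217L, gC = 256L, gD = 218L), 256L)
  de8 <- mk_de(c("gA", "gB", "gD"), c(0.01, 0.01, 0.04))  # gC not in 8vs8 set
  cons <- combine_calls(tally, de8, threshold_frac = 0.85)
  expect_equal(attr(cons, "consensus_threshold"), 218L)  # ceil(0.85 * 256)
  row <- function(g) cons[cons$gene_id == g, ]
  expect_true(row("gA")$final_de)        # in 8vs8, 220 >= 218
  expect_false(row("gB")$final_de)       # 217 < 218
  expect_false(row("gC")$final_de)       # not significant in 8vs8
  expect_true(row("gC")$systematic_4vs4) # but systematic in 4vs4
  expect_true(row("gD")$final_de)        # boundary: exactly 218

  # deterministic and independent of gene order
  tally2 <- mk_tally(rev(tally$tally), 256L)
  cons2 <- combine_calls(tally2, de8, threshold_frac = 0.85)
  m <- merge(as.data.frame(cons), as.data.frame(cons2), by = "gene_id")
  expect_equal(m$final_de.x, m$final_de.y)
  expect_equal(m$n_combos_de.x, m$n_combos_de.y)

  # union join flags genes absent from either universe
  expect_true(all(cons$in_4vs4_universe))
  expect_false(row("gC")$in_8vs8_universe)
})

test_that("4vs4 tally respects its bounds and refilters per combination", {
  # small design (2 sites/category -> 16 combos) for speed
  d <- toy_design(2)
  set.seed(71)
  G <- 120
  y <- matrix(stats::rnbinom(G * 8, size = 10, mu = 50), G, 8)
  # one gene below the filter everywhere: tally must stay 0
  y[1, ] <- c(1, 1, 1, 1, 0, 1, 1, 1)
  cm <- count_matrix(y, sprintf("g%03d", 1:G), d$library_id)
  res <- run_4vs4_all(cm, d, dispersion = "common")
  expect_equal(res$n_combos, 16L)
  expect_equal(unname(res$tally["g001"]), 0L)
  expect_true(all(res$tally >= 0 & res$tally <= res$n_combos))
  expect_true(all(res$per_combo_n_de <= G))
})

test_that("a strongly planted effect is found in every combination", {
  cfg <- sim_config(n_genes = 400, n_sites_per_category = 2, frac_de = 0.05,
                    lfc_magnitude = 4, site_sd = 0, frac_immune = 0,
                    seed = 72)
  sim <- simulate_dataset(cfg)
  res <- run_4vs4_all(sim$counts, sim$design)
  planted <- sim$truth$genes$gene_id[abs(sim$truth$genes$true_lfc) >= 4]
  hit <- res$tally[planted]
  expect_gte(mean(hit == res$n_combos), 0.9)
  expect_gte(mean(hit >= ceiling(0.85 * res$n_combos)), 0.95)
})

test_that("site variability increases between-combination disagreement for null genes", {
  # Monotone over site_sd in {0, 0.5, 1}. At a fixed (replicate-level)
  # dispersion the spread of the per-combination evidence, var(log p) across
  # replicate selections, grows strictly with the site-effect SD. (With
  # per-combination dispersion re-estimation the estimate absorbs the site
  # variance and compresses p-values toward 1 instead - the mechanism that
  # makes each 4vs4 run conservative; that direction is asserted too.)
  measure <- function(ss, phi_mode) {
    sim <- simulate_dataset(sim_config(n_genes = 250, frac_de = 0,
                                       site_sd = ss, seed = 73))
    combos <- enumerate_combinations(sim$design)[seq(1, 256, by = 16)]
    catlib <- stats::setNames(sim$design$invasion_category,
                              sim$design$library_id)
    P <- vapply(combos, function(libs) {
      sub <- filter_low_counts(sim$counts[, libs], 10)
      nf <- rle_factors(sub)
      grp <- factor(catlib[libs], c("ancient", "recent"))
      phi <- if (identical(phi_mode, "estimate"))
        estimate_common_dispersion(sub, nf, grp) else phi_mode
      pv <- stats::setNames(rep(NA_real_, 250), gene_ids(sim$counts))
      r <- comboDE:::exact_test_all(sub, grp, nf$effective_lib_size, phi)
      pv[r$gene_id] <- r$p_value
      pv
    }, numeric(250))
    c(spread = mean(apply(log(pmax(P, 1e-300)), 1, stats::var), na.rm = TRUE),
      var_p = mean(apply(P, 1, stats::var), na.rm = TRUE))
  }
  fixed <- vapply(c(0, 0.5, 1), measure, numeric(2), phi_mode = 0.1)
  expect_lt(fixed["spread", 1], fixed["spread", 2])
  expect_lt(fixed["spread", 2], fixed["spread", 3])

  # re-estimated dispersion absorbs the site variance: p-values are
  # compressed, so their raw-scale spread shrinks as site_sd grows
  est <- vapply(c(0, 1), measure, numeric(2), phi_mode = "estimate")
  expect_gt(est["var_p", 1], est["var_p", 2])
})

test_that("8vs8 and random-effects runs keep their structural contracts", {
  sim <- simulate_dataset(sim_config(n_genes = 400, frac_de = 0.05,
                                     lfc_magnitude = 3, seed = 74))
  de8 <- run_8vs8(sim$counts, sim$design)
  expect_true(all(de8$fdr >= de8$p_value))
  expect_true(all(de8$p_value >= 0 & de8$p_value <= 1))
  # FDR non-decreasing in p
  o <- order(de8$p_value)
  expect_true(all(diff(de8$fdr[o]) >= -1e-12))

  expect_message(der <- run_ranef(sim$counts, sim$design),
                 "correlation estimate")
  expect_true(all(der$fdr >= der$p_value))
  expect_true(is.finite(attr(der, "rho")))
  # both tables cover the same filtered universe
  expect_setequal(de8$gene_id, der$gene_id)
})
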