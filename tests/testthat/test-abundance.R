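test_that("abundance, breadth and the zeroing boundary", {
  full <- compute_abundance(coverage_track("g", "s", rep(5, 1000)))
  expect_equal(full$mean_depth, 5)
  expect_equal(full$breadth, 1)
  expect_false(full$zeroed)
  expect_equal(full$abundance, 5)
  ## depth 10 over 20% of positions: mean 2, breadth 0.2 -> zeroed
  sparse <- compute_abundance(coverage_track("g", "s",
                                             c(rep(10, 200), rep(0, 800))))
  expect_equal(sparse$mean_depth, 2)
  expect_equal(sparse$breadth, 0.2)
  expect_true(sparse$zeroed)
  expect_equal(sparse$abundance, 0)
  ## breadth exactly 0.25 is zeroed (boundary inclusive)
  edge <- compute_abundance(coverage_track("g", "s",
                                           c(rep(1, 250), rep(0, 750))))
  expect_equal(edge$breadth, 0.25)
  expect_true(edge$zeroed)
  just_over <- compute_abundance(coverage_track("g", "s",
                                                c(rep(1, 251), rep(0, 749))))
  expect_false(just_over$zeroed)
  expect_error(compute_abundance(coverage_track("g", "s", numeric(0))), "empty")
})

test_that("SparCC matches the 3-taxon closed form at a fixed resample seed", {
  set.seed(11)
  counts <- matrix(rpois(3 * 60, lambda = rep(c(500, 300, 200), 60)), 3, 60)
  cfg <- jumbo_config(sparcc_iterations = 1L)
  rho <- sparcc_correlations(counts, cfg, seed = 99)
  frac <- replay_dirichlet(counts, seed = 99)
  oracle <- oracle_sparcc3(frac)
  expect_lt(max(abs(rho - oracle$rho)), 1e-9)
  ## the solved basis variances equal the closed form too
  Tm <- jumbophage:::log_ratio_variances(frac)
  omega <- solve(matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3), rowSums(Tm))
  expect_lt(max(abs(omega - oracle$omega)), 1e-9)
})

test_that("correlation matrix invariants hold", {
  set.seed(12)
  ab <- generate_abundance_matrix(8, 60, NULL, seed = 12)
  cfg <- jumbo_config(sparcc_iterations = 5L)
  rho <- sparcc_correlations(ab$counts, cfg, seed = 3)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 8))
  expect_true(all(abs(rho) <= 1))
  ## compositional invariance is exact at the variance stage: scaling all
  ## counts in a sample cancels in the log ratios
  frac <- replay_dirichlet(ab$counts, 1)
  scaled <- sweep(frac, 2, runif(60, 0.5, 2), "*")
  expect_equal(jumbophage:::log_ratio_variances(frac),
               jumbophage:::log_ratio_variances(scaled))
  ## the deterministic core is invariant to taxon reordering
  Tm <- jumbophage:::log_ratio_variances(frac)
  perm <- sample(8)
  r1 <- jumbophage:::basis_correlations(Tm, matrix(FALSE, 8, 8))
  r2 <- jumbophage:::basis_correlations(Tm[perm, perm], matrix(FALSE, 8, 8))
  expect_equal(r2, r1[perm, perm])
  ## constant taxa are flagged undefined, not fabricated
  cst <- ab$counts
  cst[2, ] <- 1000L
  rc <- sparcc_correlations(cst, cfg, seed = 3)
  expect_true(all(is.na(rc[2, -2])))
  expect_equal(unname(attr(rc, "undefined_taxa")), 2L)
})

test_that("planted correlations are recovered and bootstrap-significant", {
  ab <- generate_abundance_matrix(10, 200,
                                  data.frame(i = c(1, 3), j = c(2, 4),
                                             sign = c("+", "-")), seed = 3)
  ## latent planting is as requested
  expect_gt(cor(ab$latent[1, ], ab$latent[2, ]), 0.8)
  expect_lt(cor(ab$latent[3, ], ab$latent[4, ]), -0.8)
  cfg <- jumbo_config()
  rho <- sparcc_correlations(ab$counts, cfg, seed = 3)
  expect_gt(rho[1, 2], 0.6)
  expect_lt(rho[3, 4], -0.6)
  ## reduced bootstrap for the unit test; full depth in the acceptance suite
  cfg_fast <- jumbo_config(n_bootstrap = 200L, p_cutoff = 0.01)
  p <- bootstrap_pvalues(ab$counts, rho, cfg_fast, seed = 3)
  expect_equal(p[1, 2], 0)
  expect_equal(p[3, 4], 0)
  expect_true(is.na(p[1, 1]))
  net <- build_coabundance_network(rho, p, cfg_fast)
  keys <- paste(net$pairs$i, net$pairs$j)
  expect_true(all(c("taxon_01 taxon_02", "taxon_03 taxon_04") %in% keys))
  expect_equal(net$pairs$sign[keys == "taxon_01 taxon_02"], "positive")
  expect_equal(net$pairs$sign[keys == "taxon_03 taxon_04"], "negative")
  expect_error(bootstrap_pvalues(ab$counts, rho, jumbo_config(n_bootstrap = 0L)),
               "n_boot|n_bootstrap")
})

test_that("generator validates its arguments", {
  expect_error(generate_abundance_matrix(2, 50, NULL, 1), "3 taxa")
  expect_error(generate_abundance_matrix(10, 50,
                                         data.frame(i = c(1, 1), j = c(2, 3),
                                                    sign = c("+", "+")), 1),
               "one planted pair")
  expect_error(sparcc_correlations(matrix(1, 2, 10)), ">= 3")
})

test_that("pseudo-count transform and the coabundance cutoff are strict", {
  ab <- matrix(c(1.234, 0, 2.5, 3.333), 2)
  expect_equal(abundance_pseudo_counts(ab), round(ab * 100))
  rho <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- matrix(c(NA, 0.001, 0.001, NA), 2, dimnames = dimnames(rho))
  ## p exactly at the cutoff is NOT retained
  expect_equal(nrow(build_coabundance_network(rho, p)$pairs), 0L)
})
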