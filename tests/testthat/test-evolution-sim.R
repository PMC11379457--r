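test_that("fixation odds honour the neutral, strong-selection and monotone limits", {
  expect_equal(fixation_odds(1000, 0), 0.5)
  expect_equal(fixation_odds(5, 1e-12), 0.5, tolerance = 1e-9)
  N <- 10^seq(2, 7, by = 0.25)
  odds <- fixation_odds(N, 0.001)
  expect_true(all(diff(odds) <= 0))
  # strict monotonicity holds on the log scale even where odds underflow
  expect_true(all(diff(fixation_odds(N, 0.001, log = TRUE)) < 0))
  expect_lt(fixation_odds(1e7, 0.001), 1e-8)  # Ns = 1e4
  expect_true(all(is.finite(fixation_odds(10^(0:7), 0.001))))
  expect_true(all(is.finite(fixation_odds(10^(0:7), 0.001, log = TRUE))))
  expect_true(all(is.finite(fixation_odds(1e7, c(-0.001, 0.001)))))
})

test_that("fixation probability has the right neutral limit and sign behaviour", {
  expect_equal(fixation_prob(1000, 0), 1 / 2000)
  expect_equal(fixation_prob(1000, 1e-14), 1 / 2000, tolerance = 1e-6)
  # beneficial mutations fix more often than neutral, deleterious less
  expect_gt(fixation_prob(1000, 0.01), 1 / 2000)
  expect_lt(fixation_prob(1000, -0.01), 1 / 2000)
  # odds definition agrees with the probability ratio where both are stable
  s <- 0.001; N <- 2000
  pr <- fixation_prob(N, -s) / (fixation_prob(N, -s) + fixation_prob(N, s))
  expect_equal(fixation_odds(N, s), pr, tolerance = 1e-10)
})

test_that("stationary usage equals GC expectation at s = 0 and the two-state odds for two-fold families", {
  spec <- genome_spec(g_mut = 0.6, s = 0)
  P <- stationary_usage(spec)
  expect_equal(P, expected_usage(0.6)$E, tolerance = 1e-12)
  N <- 1000
  spec2 <- genome_spec(g_mut = 0.5, sN = 3, N = N)
  P2 <- stationary_usage(spec2)
  s <- spec2$s[["Lys"]]
  expect_equal(P2[[spec2$preferred[["Lys"]]]], 1 - fixation_odds(N, s),
               tolerance = 1e-12)
})

test_that("simulated genomes are seed-deterministic and pass their own QC", {
  spec <- genome_spec(n_codons = 3000, g_mut = 0.45, sN = 2, seed = 99)
  a <- simulate_genome(spec)
  b <- simulate_genome(spec)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_equal(a$counts$qc$n_records_kept, a$counts$qc$n_records_in)
  expect_equal(a$counts$qc$n_dropped_internal_stop, 0)
  expect_equal(a$counts$qc$n_missing_terminal_stop, 0)
  # truth table records the per-family scaled selection intensity
  expect_equal(a$truth$sN[a$truth$family == "Lys"], 2, tolerance = 1e-12)
})

test_that("neutral simulated usage matches the GC expectation within families", {
  sim <- simulate_genome(genome_spec(n_codons = 60000, g_mut = 0.6, s = 0,
                                     seed = 12))
  u <- codon_usage(sim$counts)
  expect_equal(u$conditional[["AAA"]], 0.4, tolerance = 0.02)
  # chi-square against expectation, Lys family
  lys <- c("AAA", "AAG")
  obs <- sim$counts$counts[lys]
  expect_gt(stats::chisq.test(obs, p = c(0.4, 0.6))$p.value, 1e-4)
})

test_that("strong selection drives preferred two-fold codons to their stationary frequency", {
  N <- 1000
  spec <- genome_spec(n_codons = 60000, g_mut = 0.5, sN = 10, N = N, seed = 13)
  sim <- simulate_genome(spec)
  u <- codon_usage(sim$counts)
  target <- 1 - fixation_odds(N, spec$s[["Lys"]])
  pref <- spec$preferred[["Lys"]]
  n_lys <- sim$counts$family_totals[["Lys"]]
  expect_lt(abs(u$conditional[[pref]] - target),
            3 * sqrt(target * (1 - target) / n_lys) + 1e-4)
})

test_that("tree and trait simulation is deterministic and recovers the set correlation", {
  a <- simulate_tree_traits(20, rho = 0.5, seed = 3)
  b <- simulate_tree_traits(20, rho = 0.5, seed = 3)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$traits, b$traits)
  rs <- vapply(1:6, function(sd) {
    tt <- simulate_tree_traits(100, rho = 0.9, seed = 200 + sd)
    x <- stats::setNames(tt$traits$x, tt$traits$species)
    y <- stats::setNames(tt$traits$y, tt$traits$species)
    pic_correlation(tt$tree, x, y)$r
  }, 0)
  expect_lt(abs(mean(rs) - 0.9), 0.1)
  r0 <- vapply(1:6, function(sd) {
    tt <- simulate_tree_traits(100, rho = 0, seed = 300 + sd)
    pic_correlation(tt$tree, stats::setNames(tt$traits$x, tt$traits$species),
                    stats::setNames(tt$traits$y, tt$traits$species))$r
  }, 0)
  expect_lt(abs(mean(r0)), 0.15)
})

test_that("trait tables reproduce their generative components", {
  eff <- c(-0.02, 0, 0.02)
  tab <- simulate_trait_table(3, 4, domain_sd = 0, residual_sd = 0,
                              species_effects = eff, grand_mean = 0.3,
                              seed = 1)
  got <- tapply(tab$value, tab$species, mean) - 0.3
  expect_equal(as.numeric(got), eff, tolerance = 1e-12)
  tab2 <- simulate_trait_table(10, 40, seed = 2)
  truth <- attr(tab2, "truth")
  expect_length(truth$species_effects, 10)
  expect_equal(mean(truth$species_effects), 0)
  expect_equal(nrow(tab2), 400)
  # determinism
  tab3 <- simulate_trait_table(10, 40, seed = 2)
  expect_identical(tab2$value, tab3$value)
})
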