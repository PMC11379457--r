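test_that("RSCU, w and CAI match hand evaluation on a Lys-only profile", {
  r <- rscu_cai(c(AAA = 3, AAG = 1))
  expect_equal(r$rscu[["AAA"]], 1.5)
  expect_equal(r$rscu[["AAG"]], 0.5)
  expect_equal(r$w[["AAA"]], 1)
  expect_equal(r$w[["AAG"]], 1 / 3)
  expect_equal(r$cai, r$cai_raw / r$cai_max)
  # geometric mean by hand: (1^3 * (1/3)^1)^(1/4)
  expect_equal(r$cai, (1 / 3)^(1 / 4))
})

test_that("CAI hits its ceiling for single-codon-per-family usage and for uniform usage", {
  split <- split(codon_table()$codon, codon_table()$family)
  one <- vapply(split, function(x) sort(x)[1], "")
  r <- rscu_cai(stats::setNames(rep(10, 21), one))
  expect_equal(r$cai, 1)
  uni <- stats::setNames(rep(5, 64), codons())
  r2 <- rscu_cai(uni)
  expect_equal(unname(r2$rscu), rep(1, 64))
  expect_equal(r2$cai, 1)
  expect_equal(r2$cai_raw, 1)
})

test_that("CAI is invariant to duplicating every sequence", {
  set.seed(11)
  n <- stats::setNames(sample(0:50, 64, replace = TRUE), codons())
  expect_equal(rscu_cai(n)$cai, rscu_cai(2 * n)$cai)
})

test_that("standard CAIS matches hand evaluation and the KL identity", {
  # Lys-only genome, O = 0.75/0.25 vs E = 0.5/0.5
  res <- cais(c(AAA = 3, AAG = 1), g = 0.5)
  expect_equal(res$value, 0.75 * log(1.5) + 0.25 * log(0.5))
  expect_equal(sum(res$per_family), res$value)
  # zero iff conditional usage equals the expectation
  for (g in c(0.3, 0.5, 0.7)) {
    cv <- counts_at_expectation(g)
    expect_lt(abs(cais(cv, g)$value), 1e-12)
  }
  # and strictly positive otherwise
  expect_gt(cais(c(AAA = 3, AAG = 1), g = 0.5)$value, 0)
})

test_that("standard CAIS ignores family marginals; literal mode shifts by sum Fa log Pa", {
  cond <- random_conditional(101)
  m1 <- random_marginals(102)
  m2 <- random_marginals(103)
  F <- random_marginals(104)
  cv1 <- counts_from_profile(cond, m1)
  cv2 <- counts_from_profile(cond, m2)
  s1 <- cais(cv1, 0.45, aa_freqs = F)$value
  s2 <- cais(cv2, 0.45, aa_freqs = F)$value
  expect_lt(abs(s1 - s2), 1e-12)
  l1 <- cais(cv1, 0.45, aa_freqs = F, mode = "literal")$value
  l2 <- cais(cv2, 0.45, aa_freqs = F, mode = "literal")$value
  expect_gt(abs(l1 - l2), 1e-6)  # the printed form is marginal-sensitive
  expect_equal(l1 - s1, sum(F * log(m1[names(F)])), tolerance = 1e-9)
  expect_equal(l2 - s2, sum(F * log(m2[names(F)])), tolerance = 1e-9)
})

test_that("alpha re-weighting satisfies Fa = alpha * observed family frequency", {
  # literal-mode decomposition implies alpha_a = F_a / P_a
  expect_equal(0.06 / 0.05, 1.2)
  cond <- random_conditional(7)
  m <- random_marginals(8)
  F <- random_marginals(9)
  cv <- counts_from_profile(cond, m)
  u <- codon_usage(cv)
  alpha <- F / u$family_freq[names(F)]
  expect_equal(unname(alpha * u$family_freq[names(F)]), unname(F))
})

test_that("CAIS unchanged by codon-preserving shuffles of sequences", {
  set.seed(21)
  sim <- simulate_genome(genome_spec(n_codons = 3000, g_mut = 0.55, seed = 5))
  shuffled <- vapply(sim$sequences, function(s) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(sample(cod), collapse = "")
  }, "")
  qc <- qc_policy(drop_internal_stop = FALSE, warn_no_terminal_stop = FALSE)
  expect_equal(cais(count_codons(shuffled, qc), 0.55)$value,
               cais(sim$counts, 0.55)$value)
})

test_that("weighted families absent from the genome are skipped with a warning", {
  F <- stats::setNames(rep(1 / 21, 21), families())
  expect_warning(res <- cais(c(AAA = 3, AAG = 1), 0.5, aa_freqs = F),
                 "skipped")
  expect_equal(res$value, (0.75 * log(1.5) + 0.25 * log(0.5)) / 21)
})

test_that("local-GC CAIS reduces correctly for one and for duplicated regions", {
  cond <- random_conditional(31)
  m <- random_marginals(32)
  cv <- counts_from_profile(cond, m, total = 5000)
  whole <- cais(cv, 0.52, aa_freqs = m)$value
  one <- cais_local_gc(list(cv), g = 0.52, aa_freqs = m)
  expect_equal(one$value, whole, tolerance = 1e-12)
  two <- cais_local_gc(list(cv, cv), g = c(0.52, 0.52), aa_freqs = m)
  expect_equal(two$value, whole, tolerance = 1e-12)
})

test_that("local-GC CAIS aggregates regions as a codon-weighted geometric mean", {
  condA <- random_conditional(41); mA <- random_marginals(42)
  condB <- random_conditional(43); mB <- random_marginals(44)
  cvA <- counts_from_profile(condA, mA, total = 3000)
  cvB <- counts_from_profile(condB, mB, total = 9000)
  F <- random_marginals(45)
  dA <- cais(cvA, 0.4, aa_freqs = F)$value
  dB <- cais(cvB, 0.6, aa_freqs = F)$value
  LA <- cvA$L; LB <- cvB$L
  expected <- exp((LA * log(dA) + LB * log(dB)) / (LA + LB))
  got <- cais_local_gc(list(cvA, cvB), g = c(0.4, 0.6), aa_freqs = F)
  expect_equal(got$value, expected, tolerance = 1e-12)
  expect_equal(got$n_regions, 2)
  expect_equal(got$n_dropped, 0)
})

test_that("regions with non-positive inner divergence are dropped and counted", {
  # a two-family genome keeps the (negative) family-entropy term of literal
  # mode small enough for a strongly biased region to overcome it ...
  good <- codon_counts(c(AAA = 1000, GGG = 1000))
  # ... while a region at the GC expectation cannot: its literal divergence
  # is exactly the negative family entropy
  F <- stats::setNames(numeric(21), families()); F[c("Lys", "Gly")] <- 0.5
  bad <- counts_at_expectation(0.5, total = 2000, marginals = F)
  expect_lt(cais(bad, 0.5, aa_freqs = F, mode = "literal")$value, 0)
  res <- cais_local_gc(list(good, bad), g = c(0.5, 0.5), aa_freqs = F,
                       mode = "literal")
  expect_equal(res$n_dropped, 1)
  expect_equal(res$value,
               cais(good, 0.5, aa_freqs = F, mode = "literal")$value,
               tolerance = 1e-12)
  expect_error(cais_local_gc(list(bad), g = 0.5, aa_freqs = F,
                             mode = "literal"),
               "all regions dropped")
})

test_that("CAI is confounded with GC: it peaks at g = 0.5 and falls on both limbs", {
  # deterministic usage at the mutational expectation: no selection at all,
  # yet CAI varies strongly with g (V-shaped around 0.5), so AT-rich
  # genomes (the realistic vertebrate range) show a strong positive CAI-GC
  # correlation; CAIS stays at zero throughout
  gs <- seq(0.3, 0.7, by = 0.05)
  vals <- vapply(gs, function(g) {
    cv <- counts_at_expectation(g, total = 1e6)
    c(rscu_cai(cv)$cai, cais(cv, g)$value)
  }, numeric(2))
  lo <- gs <= 0.5
  expect_gt(stats::cor(gs[lo], vals[1, lo]), 0.9)
  expect_lt(stats::cor(gs[!lo], vals[1, !lo]), -0.9)
  expect_equal(which.max(vals[1, ]), which(gs == 0.5))
  expect_true(all(abs(vals[2, ]) < 1e-12))
})

test_that("ENC reaches 64 at uniform usage and 21 at one codon per family", {
  uni <- codon_counts(stats::setNames(rep(round(1e5 / 64), 64), codons()))
  e <- enc(uni, 0.5)
  expect_lt(abs(e$enc - 64), 0.5)
  split <- split(codon_table()$codon, codon_table()$family)
  one <- vapply(split, function(x) sort(x)[1], "")
  e21 <- enc(codon_counts(stats::setNames(rep(100, 21), one)), 0.5)
  expect_equal(e21$enc, 21)
  expect_equal(unname(e21$f_corrected[!is.na(e21$f_corrected)]),
               rep(1, 19))
})

test_that("families with a single observation are excluded from class means", {
  counts <- stats::setNames(rep(50, 64), codons())
  counts[c("AAA", "AAG")] <- c(1, 0)  # Lys observed once
  e <- enc(codon_counts(counts), 0.5)
  expect_true(is.na(e$f_corrected[["Lys"]]))
  # class-2 mean computed over the 8 remaining two-fold families
  twofold <- setdiff(degeneracy_classes()[["2"]], "Lys")
  expect_equal(e$class_means[["2"]], mean(e$f_corrected[twofold]))
})

test_that("an empty degeneracy class falls back to its null mean with a flag", {
  e <- enc(c(AAA = 30, AAG = 10, GGG = 20, GGA = 20), 0.5)
  expect_true(e$low_confidence)
  expect_equal(e$class_means[["6"]], 1 / 6)
  expect_equal(e$class_means[["3"]], 1 / 3)
})

test_that("ENC chi-square follows its definition on a hand-checked family", {
  # Lys 30/10 at g=0.5: X2 = 40 * ((0.75-0.5)^2/0.5 + (0.25-0.5)^2/0.5) = 10
  e <- enc(c(AAA = 30, AAG = 10, GGG = 20, GGA = 20, GGC = 20, GGT = 20), 0.5)
  expect_equal(e$chi2[["Lys"]], 10)
  expect_equal(e$f_corrected[["Lys"]], (10 + 40 - 2) / (2 * 39))
  expect_equal(e$chi2[["Gly"]], 0)
  expect_equal(e$f_corrected[["Gly"]], (80 - 4) / (4 * 79))
})
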