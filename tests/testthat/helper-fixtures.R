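# Shared fixtures: analytic usage profiles and small synthetic genomes.

# Counts whose within-family conditional usage equals the GC expectation
# exactly; family marginals default to equal weight per family.
counts_at_expectation <- function(g, total = 1e6, marginals = NULL) {
  eu <- expected_usage(g)
  tab <- codon_table()
  if (is.null(marginals)) {
    marginals <- stats::setNames(rep(1 / 21, 21), families())
  }
  n <- eu$E * as.numeric(marginals[tab$family]) * total
  codon_counts(stats::setNames(n, tab$codon))
}

# Counts with an arbitrary (seeded) within-family conditional profile and
# chosen family marginals.
counts_from_profile <- function(conditional, marginals, total = 1e6) {
  tab <- codon_table()
  codon_counts(stats::setNames(
    conditional * as.numeric(marginals[tab$family]) * total, tab$codon))
}

random_conditional <- function(seed) {
  set.seed(seed)
  tab <- codon_table()
  x <- stats::rgamma(64, shape = 2)
  fam_sum <- tapply(x, tab$family, sum)
  stats::setNames(x / as.vector(fam_sum[tab$family]), tab$codon)
}

random_marginals <- function(seed) {
  set.seed(seed)
  m <- stats::rgamma(21, shape = 5)
  stats::setNames(m / sum(m), families())
}

# Brute-force phylogenetic GLS slope (with intercept) of y on x under
# Brownian covariance given by shared branch lengths -- the independent
# oracle for the contrast regression.
pgls_slope <- function(tree, x, y) {
  C <- ape::vcv(tree)
  ord <- rownames(C)
  X <- cbind(1, x[ord])
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y[ord])
  beta[2]
}

# A deterministic genome string with known GC content (alternating pattern).
pattern_genome <- function(len, pattern = "ACGT", name = "chr1") {
  s <- paste(rep(pattern, ceiling(len / nchar(pattern))), collapse = "")
  Biostrings::DNAStringSet(stats::setNames(substr(s, 1, len), name))
}
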