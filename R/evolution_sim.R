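# Stationary mutation-selection-drift simulator for validating the metrics,
# plus Brownian traits on trees and species-by-domain trait tables.
#
# Sites are independent (no linkage): each codon site sits at the
# stationary distribution of a fix/counter-fix process in a diploid
# Wright-Fisher population of size N, with GC-biased mutation and weak
# selection s in favor of one preferred codon per family.

#' Fixation probability of a new mutation
#'
#' Diploid Wright-Fisher approximation for |s| << 1:
#' \eqn{\pi(N, s) = (1 - e^{-s/2}) / (1 - e^{-Ns})}, with the neutral limit
#' \eqn{1/(2N)} as \eqn{s \to 0}.
#'
#' @param N Population size (>= 1).
#' @param s Selection coefficient of the mutation.
#' @return Fixation probability; vectorized over both arguments.
#' @export
fixation_prob <- function(N, s) {
  stopifnot(all(N >= 1))
  out <- ifelse(abs(s) < 1e-12, 1 / (2 * N),
                -expm1(-s / 2) / -expm1(-N * s))
  as.numeric(out)
}

#' Long-term odds of a site being fixed for the deleterious allele
#'
#' For symmetric mutation between a preferred and a non-preferred allele,
#' the fraction of time spent fixed for the deleterious state is
#' \eqn{\pi(N, -s) / (\pi(N, -s) + \pi(N, s))}, which simplifies
#' analytically to \eqn{1 / (1 + e^{s(N - 1/2)})} under the fixation model
#' above -- overflow-safe for any \eqn{Ns}. Equals 1/2 as \eqn{s \to 0}
#' (drift dominates), strictly decreases with \eqn{Ns}, and tends to 0 for
#' \eqn{Ns \gg 1} (selection purges the deleterious state). Only a narrow
#' band of intermediate \eqn{sN} gives intermediate codon bias.
#'
#' @param N Population size (>= 1).
#' @param s Selection coefficient against the deleterious allele (s > 0
#'   means the preferred allele is favored).
#' @param log Return the log odds (exact even where the odds underflow,
#'   e.g. Ns of several thousand).
#' @return Odds in (0, 0.5] for s >= 0; vectorized.
#' @examples
#' fixation_odds(1e4, 0.001)
#' @export
fixation_odds <- function(N, s, log = FALSE) {
  stopifnot(all(N >= 1))
  stats::plogis(-s * (N - 0.5), log.p = log)
}

#' Specification of a stationary simulated genome
#'
#' @param n_codons Approximate total codons (across genes, including each
#'   gene's start ATG and stop codon).
#' @param g_mut GC mutational bias in (0, 1): mutation pressure alone drives
#'   codon frequencies toward weights \eqn{(g/2)^{k_{GC}}
#'   ((1-g)/2)^{k_{AT}}} within each family.
#' @param N Population size.
#' @param s Selection coefficient favoring the preferred codon: a scalar,
#'   or a named per-family vector.
#' @param sN Convenience: when given, s is set to \code{sN / (N - 0.5)} so
#'   the scaled intensity is exact under the fixation model.
#' @param preferred Named character vector, preferred codon per family;
#'   default takes the alphabetically first codon of each family.
#' @param gene_length Codons per gene (default 300).
#' @param family_weights Site allocation over non-STOP families; default
#'   proportional to family size.
#' @param seed Integer seed; fully determines the simulated genome.
#' @return Object of class \code{"genome_spec"}.
#' @export
genome_spec <- function(n_codons = 10000L, g_mut = 0.5, N = 1000,
                        s = 0, sN = NULL, preferred = NULL,
                        gene_length = 300L, family_weights = NULL,
                        seed = NULL) {
  if (g_mut <= 0 || g_mut >= 1) stop("g_mut must lie in (0, 1)")
  if (!is.null(sN)) s <- sN / (N - 0.5)
  fams <- families()
  s_vec <- stats::setNames(rep(0, length(fams)), fams)
  if (length(s) == 1L && is.null(names(s))) {
    s_vec[] <- s
  } else {
    if (any(!names(s) %in% fams)) stop("unknown family in s")
    s_vec[names(s)] <- s
  }
  split <- .family_split()
  if (is.null(preferred)) {
    preferred <- vapply(split, function(x) sort(x)[1], character(1))
  } else {
    if (any(!names(preferred) %in% fams)) stop("unknown family in preferred")
    pref <- vapply(split, function(x) sort(x)[1], character(1))
    pref[names(preferred)] <- preferred
    bad <- vapply(fams, function(a) !(pref[[a]] %in% split[[a]]), logical(1))
    if (any(bad)) stop("preferred codon outside its family: ",
                       paste(fams[bad], collapse = ", "))
    preferred <- pref
  }
  nonstop <- setdiff(fams, "STOP")
  if (is.null(family_weights)) {
    n_a <- vapply(split[nonstop], length, integer(1))
    family_weights <- n_a / sum(n_a)
  } else {
    family_weights <- family_weights[nonstop] / sum(family_weights[nonstop])
  }
  structure(list(n_codons = as.integer(n_codons), g_mut = g_mut, N = N,
                 s = s_vec, preferred = preferred[fams],
                 gene_length = as.integer(gene_length),
                 family_weights = family_weights, seed = seed),
            class = "genome_spec")
}

#' Stationary within-family codon distributions of a genome spec
#'
#' Each family's stationary distribution is
#' \eqn{P(i) \propto w_i \exp(S_a \cdot 1[i = \mathrm{preferred}])} with
#' mutational weights \eqn{w_i = (g/2)^{k_{GC}} ((1-g)/2)^{k_{AT}}} and
#' scaled selection \eqn{S_a = s_a (N - 1/2)}. At s = 0 this is exactly the
#' GC-expected usage; for a two-codon family with symmetric mutation the
#' preferred codon's frequency is exactly \eqn{1 -
#' \mathrm{fixation\_odds}(N, s)}.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @return Named numeric vector over the 64 codons; sums to 1 within each
#'   family.
#' @export
stationary_usage <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  eu <- expected_usage(spec$g_mut)
  tab <- codon_table()
  S <- spec$s[tab$family] * (spec$N - 0.5)
  boost <- ifelse(tab$codon == spec$preferred[tab$family], exp(S), 1)
  w <- eu$E[tab$codon] * boost
  fam_sum <- tapply(w, tab$family, sum)
  P <- w / as.vector(fam_sum[tab$family])
  stats::setNames(as.numeric(P), tab$codon)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a genome of coding sequences at mutation-selection-drift balance
#'
#' Every codon site is drawn independently from its family's stationary
#' distribution (\code{\link{stationary_usage}}). Sequences are organized
#' into genes of \code{gene_length} codons: a forced initial ATG, a body of
#' non-STOP family sites allocated by \code{family_weights}, and a terminal
#' stop codon drawn from the STOP family's stationary distribution (so the
#' output passes internal-stop QC).
#'
#' @param spec A \code{\link{genome_spec}}; \code{spec$seed} makes the
#'   output fully reproducible.
#' @return List of class \code{"sim_genome"}: \code{sequences} (named
#'   character vector of CDS), \code{counts} (\code{codon_counts} over the
#'   genome), \code{truth} (per-family data.frame with s, sN, preferred and
#'   stationary frequencies), \code{spec}.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  P <- stationary_usage(spec)
  if (any(P < 0) || any(!is.finite(P))) stop("invalid stationary distribution")
  split <- .family_split()
  nonstop <- setdiff(families(), "STOP")
  .with_seed(spec$seed, {
    n_genes <- max(1L, round(spec$n_codons / spec$gene_length))
    body_len <- spec$gene_length - 2L
    n_body <- n_genes * body_len
    fam_draw <- sample(nonstop, n_body, replace = TRUE,
                       prob = spec$family_weights[nonstop])
    body <- character(n_body)
    for (a in unique(fam_draw)) {
      idx <- which(fam_draw == a)
      cods <- split[[a]]
      body[idx] <- sample(cods, length(idx), replace = TRUE, prob = P[cods])
    }
    stops <- sample(split[["STOP"]], n_genes, replace = TRUE,
                    prob = P[split[["STOP"]]])
    gene_of <- rep(seq_len(n_genes), each = body_len)
    bodies <- vapply(base::split(body, gene_of), paste0, character(1),
                     collapse = "")
    seqs <- stats::setNames(paste0("ATG", bodies, stops),
                            sprintf("gene_%04d", seq_len(n_genes)))
  })
  cv <- count_codons(seqs, qc = qc_policy())
  fams <- families()
  truth <- data.frame(
    family = fams,
    n_a = vapply(split[fams], length, integer(1)),
    s = spec$s[fams],
    sN = spec$s[fams] * (spec$N - 0.5),
    preferred = spec$preferred[fams],
    preferred_freq = vapply(fams, function(a) P[[spec$preferred[[a]]]],
                            numeric(1)),
    row.names = NULL)
  structure(list(sequences = seqs, counts = cv, truth = truth, spec = spec),
            class = "sim_genome")
}

#' Write simulated coding sequences as FASTA
#'
#' @param sim A \code{sim_genome} (or named character vector of sequences).
#' @param path Output FASTA path.
#' @export
write_sim_fasta <- function(sim, path) {
  seqs <- if (inherits(sim, "sim_genome")) sim$sequences else sim
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Simulate a pure-birth tree with two correlated Brownian traits
#'
#' @param n_species Number of tips (>= 3).
#' @param rho Correlation of the two traits' Brownian increments.
#' @param sigma Length-2 diffusion standard deviations per unit branch
#'   length.
#' @param birth Speciation rate of the pure-birth tree.
#' @param seed Integer seed.
#' @return List: \code{tree} (an \code{ape} phylo with branch lengths),
#'   \code{traits} (data.frame species, x, y), \code{rho}.
#' @export
simulate_tree_traits <- function(n_species, rho = 0, sigma = c(1, 1),
                                 birth = 1, seed = NULL) {
  stopifnot(n_species >= 3, abs(rho) <= 1)
  .with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = birth, death = 0)
    V <- ape::vcv(tree)
    Lv <- t(chol(V))
    Sig <- matrix(c(sigma[1]^2, rho * sigma[1] * sigma[2],
                    rho * sigma[1] * sigma[2], sigma[2]^2), 2)
    A <- chol(Sig)
    Z <- matrix(stats::rnorm(2 * n_species), n_species, 2)
    X <- Lv %*% Z %*% A
    traits <- data.frame(species = rownames(V), x = X[, 1], y = X[, 2],
                         row.names = NULL)
  })
  list(tree = tree, traits = traits, rho = rho)
}

#' Simulate a species-by-domain trait table
#'
#' Emulates a per-domain trait (such as intrinsic structural disorder)
#' measured for every protein domain in every species: value = domain
#' random intercept + species effect + residual noise, all Gaussian.
#' Default variance components follow the scale reported for vertebrate
#' disorder (among-domain sd 0.178, residual sd 0.058).
#'
#' @param n_species,n_domains Table dimensions (both >= 2); the design is
#'   balanced.
#' @param domain_sd Standard deviation of domain random intercepts.
#' @param residual_sd Residual standard deviation.
#' @param species_effects Numeric vector of true species effects (length
#'   \code{n_species}); default draws them with sd 0.02, centered.
#' @param grand_mean Baseline trait value (default 0.3).
#' @param seed Integer seed.
#' @return data.frame (species, domain, value) with the generative truth in
#'   \code{attr(, "truth")}.
#' @export
simulate_trait_table <- function(n_species, n_domains, domain_sd = 0.178,
                                 residual_sd = 0.058,
                                 species_effects = NULL, grand_mean = 0.3,
                                 seed = NULL) {
  stopifnot(n_species >= 2, n_domains >= 2)
  .with_seed(seed, {
    if (is.null(species_effects)) {
      species_effects <- stats::rnorm(n_species, 0, 0.02)
    }
    stopifnot(length(species_effects) == n_species)
    species_effects <- species_effects - mean(species_effects)
    dom_int <- stats::rnorm(n_domains, 0, domain_sd)
    sp <- sprintf("sp_%03d", seq_len(n_species))
    dm <- sprintf("dom_%04d", seq_len(n_domains))
    df <- expand.grid(species = sp, domain = dm, stringsAsFactors = FALSE)
    df$value <- grand_mean + dom_int[match(df$domain, dm)] +
      species_effects[match(df$species, sp)] +
      stats::rnorm(nrow(df), 0, residual_sd)
  })
  attr(df, "truth") <- list(species_effects = stats::setNames(species_effects, sp),
                            domain_intercepts = stats::setNames(dom_int, dm),
                            domain_sd = domain_sd, residual_sd = residual_sd,
                            grand_mean = grand_mean)
  df
}
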