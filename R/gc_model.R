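# GC content and GC-conditional expected codon usage.
#
# The null model: with no bias between C and G, nor between A and T, nor any
# pattern beyond single-nucleotide composition, a nucleotide is G or C with
# probability g, and each of the two GC (or AT) bases is equally likely.

#' Genome-wide GC content
#'
#' @param x Genome sequences: a FASTA path, a \code{DNAStringSet}, or a
#'   character vector. Ambiguous bases are excluded from both numerator and
#'   denominator.
#' @return Object of class \code{"gc_composition"}: list with \code{g}
#'   (proportion G+C among unambiguous bases), \code{n_sites} and
#'   \code{scope}.
#' @export
global_gc <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  freq <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  n <- sum(freq)
  if (n == 0) stop("no unambiguous A/C/G/T bases: GC content undefined")
  gc_composition((freq[["G"]] + freq[["C"]]) / n, n_sites = n,
                 scope = "global")
}

#' Construct a GC composition
#'
#' @param g Proportion of G+C nucleotides, in [0, 1].
#' @param n_sites Number of sites the estimate is based on.
#' @param scope \code{"global"} or \code{"regional"}.
#' @return Object of class \code{"gc_composition"}.
#' @export
gc_composition <- function(g, n_sites = NA_integer_, scope = "global") {
  g <- as.numeric(g)
  if (length(g) != 1L || is.na(g) || g < 0 || g > 1) {
    stop("g must be a single value in [0, 1]")
  }
  structure(list(g = g, n_sites = n_sites, scope = scope),
            class = "gc_composition")
}

#' @export
print.gc_composition <- function(x, ...) {
  cat(sprintf("GC composition (%s): g = %.4f over %s sites\n",
              x$scope, x$g, format(x$n_sites, big.mark = ",")))
  invisible(x)
}

.as_g <- function(g) {
  if (inherits(g, "gc_composition")) g <- g$g
  g <- as.numeric(g)
  if (length(g) != 1L || is.na(g)) stop("g must be a single numeric value")
  g
}

#' Expected codon usage under a GC content
#'
#' Under the single-nucleotide composition null, the probability of a codon
#' with \eqn{k_{GC}} G/C positions is \eqn{p_i = (g/2)^{k_{GC}}
#' ((1-g)/2)^{k_{AT}}}; the expected probability that a family's amino acid
#' is encoded by codon \eqn{i} is \eqn{E_{i|a} = p_i / \sum_{j \in a} p_j}.
#'
#' @param g GC content in (0, 1) (boundary values rejected: expectations are
#'   degenerate there), or a \code{gc_composition}.
#' @return Object of class \code{"expected_usage"}: \code{p} (64 codon
#'   probabilities summing to 1), \code{E} (within-family expectations, each
#'   family summing to 1, all strictly positive) and \code{g}.
#' @examples
#' eu <- expected_usage(0.6)
#' eu$E[["AAA"]]  # 0.4
#' @export
expected_usage <- function(g) {
  g <- .as_g(g)
  if (g <= 0 || g >= 1) {
    stop("g must lie strictly between 0 and 1 for expected usage")
  }
  sig <- gc_signature(codons())
  p <- (g / 2)^sig$k_gc * ((1 - g) / 2)^sig$k_at
  names(p) <- codons()
  tab <- codon_table()
  fam_sum <- tapply(p[tab$codon], tab$family, sum)
  E <- p / as.vector(fam_sum[tab$family])
  names(E) <- tab$codon
  structure(list(p = p, E = E, g = g), class = "expected_usage")
}
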