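# Standard nuclear genetic code tables shared by every metric.
#
# The code is data-driven: the canonical table lives both here (constructed
# from Biostrings::GENETIC_CODE at load time) and as a packaged TSV
# (inst/extdata/standard_genetic_code.tsv) so it can be asserted against and,
# in future, swapped for alternative codes.

.cais_env <- new.env(parent = emptyenv())

#' All 64 DNA codons in a fixed lexicographic (ACGT) order
#'
#' @return Character vector of length 64.
#' @export
codons <- function() {
  if (is.null(.cais_env$codons)) {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
    .cais_env$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .cais_env$codons
}

#' The standard genetic code as a codon/family table
#'
#' Stop codons (TAA, TAG, TGA) are grouped into a single \code{STOP} family
#' and treated as a three-codon "amino acid" throughout the package, because
#' mammalian genomes show documented preferences among stop codons. Amino
#' acid families are labelled with three-letter codes.
#'
#' @return A data.frame with columns \code{codon}, \code{family} (20 amino
#'   acids plus \code{STOP}) and \code{n_a}, the number of synonymous codons
#'   in the codon's family.
#' @export
codon_table <- function() {
  if (is.null(.cais_env$table)) {
    cods <- codons()
    one <- Biostrings::GENETIC_CODE[cods]
    fam <- ifelse(one == "*", "STOP", unname(Biostrings::AMINO_ACID_CODE[one]))
    n_a <- as.vector(table(fam)[fam])
    .cais_env$table <- data.frame(codon = cods, family = fam, n_a = n_a,
                                  stringsAsFactors = FALSE)
  }
  .cais_env$table
}

.family_map <- function() {
  tab <- codon_table()
  stats::setNames(tab$family, tab$codon)
}

#' Amino-acid family of a codon
#'
#' @param codon Character vector of 3-letter DNA codons (case-insensitive).
#' @return Character vector of family labels; stop codons map to
#'   \code{"STOP"}.
#' @examples
#' family_of(c("AAA", "TAA"))
#' @export
family_of <- function(codon) {
  codon <- toupper(as.character(codon))
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (need 3-letter A/C/G/T strings)")
  }
  unname(.family_map()[codon])
}

#' GC composition signature of a codon
#'
#' Counts the number of G/C and A/T positions of each codon; these exponents
#' drive the GC-conditional expected codon usage.
#'
#' @param codon Character vector of 3-letter DNA codons.
#' @return data.frame with columns \code{codon}, \code{k_gc}, \code{k_at};
#'   \code{k_gc + k_at == 3} always.
#' @export
gc_signature <- function(codon) {
  codon <- toupper(as.character(codon))
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "))
  }
  k_gc <- vapply(strsplit(codon, ""), function(x) sum(x %in% c("G", "C")), 0L)
  data.frame(codon = codon, k_gc = k_gc, k_at = 3L - k_gc,
             stringsAsFactors = FALSE)
}

#' Degeneracy classes of the standard code
#'
#' Partitions the 21 families (20 amino acids + STOP) by family size.
#' In the standard code the classes contain 2 single-codon families (Met,
#' Trp), 9 two-fold, 2 three-fold (Ile and STOP), 5 four-fold and 3 six-fold
#' families; the three-fold class containing STOP is what changes the ENC
#' three-fold coefficient from 1 to 2.
#'
#' @return Named list mapping class size ("1", "2", "3", "4", "6") to the
#'   family labels in that class.
#' @export
degeneracy_classes <- function() {
  tab <- unique(codon_table()[, c("family", "n_a")])
  split(tab$family, tab$n_a)
}

#' Families of the standard code
#' @return Character vector of the 21 family labels.
#' @export
families <- function() sort(unique(codon_table()$family))

# per-family codon index, memoized
.family_split <- function() {
  if (is.null(.cais_env$split)) {
    tab <- codon_table()
    .cais_env$split <- split(tab$codon, tab$family)
  }
  .cais_env$split
}
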