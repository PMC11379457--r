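# Species-level codon adaptation metrics.
#
# Three metrics, three confounders:
#   * CAI  -- normalized geometric mean of relative adaptiveness w_i; a
#     within-species workhorse, but confounded with GC content across
#     species (the species-wide bias also sits in its normalizing
#     denominator).
#   * CAIS -- Kullback-Leibler divergence of observed codon usage from the
#     usage expected under the genome's GC content, standardized to a
#     reference amino acid composition; natural log throughout.
#   * ENC  -- effective number of codons corrected for GC content, with the
#     stop codons included as a three-codon family (range 21-64 rather
#     than the classic 20-61).

.as_counts <- function(x) {
  if (inherits(x, "codon_counts")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(codon_counts(x))
  stop("expected a codon_counts object or a named count vector")
}

# ---------------------------------------------------------------- RSCU / CAI

#' Relative synonymous codon usage, relative adaptiveness and CAI
#'
#' \eqn{RSCU_i = N_i / (N_a / n_a)}; \eqn{w_i = RSCU_i / \max_{j \in a}
#' RSCU_j}; CAI is the geometric mean of \eqn{w_i} over all L codon
#' observations, equivalently \eqn{CAI_{raw}/CAI_{max}} where
#' \eqn{CAI_{raw}} is the geometric mean of observed RSCU values and
#' \eqn{CAI_{max}} that of the family maxima. Start and stop codons are
#' included. Geometric means use log-sums for numerical stability; codons
#' with zero counts never enter the observed product.
#'
#' @param cv \code{\link{codon_counts}} (or named count vector) with
#'   \code{L > 0}.
#' @return Object of class \code{"cai_result"}: \code{rscu}, \code{w}
#'   (NA for codons of unobserved families), \code{cai_raw},
#'   \code{cai_max}, \code{cai}, \code{L}.
#' @examples
#' rscu_cai(c(AAA = 3, AAG = 1))$w  # w_AAA = 1, w_AAG = 1/3
#' @export
rscu_cai <- function(cv) {
  cv <- .as_counts(cv)
  if (cv$L == 0L) stop("CAI undefined: no codons counted (L = 0)")
  tab <- codon_table()
  N <- cv$counts[tab$codon]
  fam_tot <- cv$family_totals[tab$family]
  rscu <- ifelse(fam_tot > 0, N / (fam_tot / tab$n_a), NA_real_)
  names(rscu) <- tab$codon
  rscu_max <- tapply(rscu, tab$family, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  rmax <- as.vector(rscu_max[tab$family])
  w <- rscu / rmax
  names(w) <- tab$codon
  obs <- N > 0
  log_raw <- sum(N[obs] * log(rscu[obs])) / cv$L
  log_max <- sum(N[obs] * log(rmax[obs])) / cv$L
  structure(list(rscu = rscu, w = w,
                 cai_raw = exp(log_raw), cai_max = exp(log_max),
                 cai = exp(log_raw - log_max), L = cv$L),
            class = "cai_result")
}

#' @export
print.cai_result <- function(x, ...) {
  cat(sprintf("CAI = %.4f (raw %.4f / max %.4f), L = %d codons\n",
              x$cai, x$cai_raw, x$cai_max, x$L))
  invisible(x)
}

# ------------------------------------------------- amino-acid frequencies F_a

#' Amino-acid family frequencies of a dataset
#'
#' Pools codon counts over one or more species and returns the frequency
#' \eqn{F_a} of each family (20 amino acids + STOP), the standardized
#' composition against which CAIS is re-weighted.
#'
#' @param x A \code{codon_counts} object or a list of them.
#' @return Named numeric vector over the 21 families, summing to 1.
#' @export
aa_frequencies <- function(x) {
  if (inherits(x, "codon_counts")) x <- list(x)
  tot <- Reduce(`+`, lapply(x, function(cv) .as_counts(cv)$family_totals))
  if (sum(tot) == 0) stop("no codons in dataset")
  tot / sum(tot)
}

#' Read an amino-acid frequency table
#'
#' @param path TSV with columns family and frequency (header optional);
#'   frequencies must sum to 1 within 1e-9.
#' @return Named numeric vector over families.
#' @export
read_aa_freqs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.numeric(df[[2]])) {  # header present
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  }
  f <- stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  if (any(!names(f) %in% families())) {
    stop("unknown family label(s): ",
         paste(setdiff(names(f), families()), collapse = ", "))
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop(sprintf("family frequencies sum to %.12f, not 1", sum(f)))
  }
  full <- stats::setNames(numeric(length(families())), families())
  full[names(f)] <- f
  full
}

.check_aa_freqs <- function(aa_freqs) {
  full <- stats::setNames(numeric(length(families())), families())
  if (any(!names(aa_freqs) %in% families())) {
    stop("unknown family label(s) in aa_freqs")
  }
  full[names(aa_freqs)] <- aa_freqs
  if (abs(sum(full) - 1) > 1e-6) stop("aa_freqs must sum to 1")
  full
}

# ------------------------------------------------------------------- CAIS

# Core divergence of one count vector against GC expectations.
# standard: sum_a F_a * KL(O_{.|a} || E_{.|a})  -- invariant to family
#           marginals by construction.
# literal:  sum_i f'_i log(O_i / E_{i|a}) with O_i the *global* codon
#           frequency and f'_i = alpha_a O_i, alpha_a = F_a / P_a -- the
#           re-weighted divergence exactly as printed, which retains a
#           dependence on family marginals (it equals the standard form
#           plus sum_a F_a log P_a) and can be negative.
# 0 * log 0 is 0 throughout; no pseudocounts.
.cais_core <- function(cv, eu, aa_freqs, mode) {
  usage <- codon_usage(cv)
  tab <- codon_table()
  fam <- tab$family
  per_family <- stats::setNames(numeric(length(families())), families())
  skipped <- character(0)
  for (a in families()) {
    Fa <- aa_freqs[[a]]
    if (Fa == 0) next
    idx <- which(fam == a)
    Oc <- usage$conditional[idx]
    if (all(is.na(Oc))) {  # family absent from the genome
      skipped <- c(skipped, a)
      next
    }
    E <- eu$E[idx]
    pos <- Oc > 0
    kl <- sum(Oc[pos] * log(Oc[pos] / E[pos]))
    if (mode == "standard") {
      per_family[[a]] <- Fa * kl
    } else {
      Pa <- usage$family_freq[[a]]
      per_family[[a]] <- Fa * (kl + log(Pa))
    }
  }
  if (length(skipped)) {
    warning("family(ies) absent from genome but weighted in aa_freqs, skipped: ",
            paste(skipped, collapse = ", "))
  }
  list(value = sum(per_family), per_family = per_family, skipped = skipped)
}

#' Codon Adaptation Index of Species (CAIS)
#'
#' Measures how far a species' synonymous codon usage departs from the
#' usage expected under its genomic GC content, re-weighted to a standard
#' amino-acid composition so that differences in amino-acid frequencies
#' among species do not affect the score.
#'
#' Two modes are provided. \code{"standard"} (default) computes
#' \eqn{\sum_a F_a \sum_{i \in a} O_{i|a} \ln(O_{i|a}/E_{i|a})}, a
#' weighted within-family Kullback-Leibler divergence: non-negative, zero
#' exactly when conditional usage matches the GC expectation, and invariant
#' to amino-acid composition by construction. \code{"literal"} computes the
#' re-weighted divergence with global codon frequencies inside the log
#' ratio, \eqn{\sum_i f'_i \ln(O_i/E_{i|a})} with \eqn{f'_i = \alpha_a
#' O_i} and \eqn{\alpha_a = F_a / P_a}; this form retains a dependence on
#' family marginals (the two modes differ by \eqn{\sum_a F_a \ln P_a}).
#'
#' @param cv \code{\link{codon_counts}} (or named count vector).
#' @param g Genomic GC content in (0, 1), or a \code{gc_composition}.
#' @param aa_freqs Standardized family frequencies \eqn{F_a} (named vector
#'   over the 21 families, summing to 1); defaults to the observed family
#'   frequencies of \code{cv} itself, appropriate for single-species use;
#'   pass \code{\link{aa_frequencies}} of the whole dataset for
#'   cross-species comparisons.
#' @param mode \code{"standard"} or \code{"literal"}.
#' @return Object of class \code{"cais_result"}: \code{value},
#'   \code{mode}, \code{per_family} (contributions summing to
#'   \code{value}), \code{g_used}, \code{L}.
#' @examples
#' cais(c(AAA = 3, AAG = 1), g = 0.5)
#' @export
cais <- function(cv, g, aa_freqs = NULL, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  cv <- .as_counts(cv)
  if (cv$L == 0L) stop("CAIS undefined: no codons counted (L = 0)")
  eu <- if (inherits(g, "expected_usage")) g else expected_usage(g)
  if (is.null(aa_freqs)) {
    aa_freqs <- cv$family_totals / cv$L
  } else {
    aa_freqs <- .check_aa_freqs(aa_freqs)
  }
  core <- .cais_core(cv, eu, aa_freqs, mode)
  structure(list(value = core$value, mode = mode,
                 per_family = core$per_family, g_used = eu$g, L = cv$L,
                 skipped_families = core$skipped),
            class = "cais_result")
}

#' @export
print.cais_result <- function(x, ...) {
  cat(sprintf("CAIS = %.6f (mode %s, g = %.4f, L = %s)\n",
              x$value, x$mode, x$g_used, format(x$L, big.mark = ",")))
  if (!is.null(x$n_regions)) {
    cat(sprintf("  local-GC aggregation over %d region(s), %d dropped\n",
                x$n_regions, x$n_dropped))
  }
  invisible(x)
}

#' CAIS corrected for local non-coding GC content
#'
#' Computes each region's divergence against expectations from its own
#' non-coding GC content, then aggregates as a codon-count-weighted
#' geometric mean over regions, \eqn{\exp(\sum_r L_r \ln d_r / L)}. With a
#' single region spanning the whole genome this reduces to the
#' whole-genome CAIS of the same mode.
#'
#' @param regions A \code{\link{build_regions}} result carrying per-region
#'   codon counts, or a list of \code{codon_counts}; in the latter case
#'   \code{g} supplies the per-region GC contents.
#' @param g Numeric vector of per-region GC contents (only when
#'   \code{regions} is a plain list).
#' @param aa_freqs Standardized family frequencies; default pools the
#'   retained regions' own counts.
#' @param mode Inner divergence mode, as in \code{\link{cais}}. Regions
#'   whose inner divergence is not positive (possible in literal mode, or
#'   for degenerate counts) are dropped from the geometric mean and
#'   counted.
#' @return Object of class \code{"cais_result"} with \code{mode =
#'   "local_gc"}, per-region divergences, and drop counts.
#' @export
cais_local_gc <- function(regions, g = NULL, aa_freqs = NULL,
                          mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (inherits(regions, "gc_regions")) {
    if (is.null(regions$counts)) {
      stop("regions carry no codon counts; rebuild with cds_seqs")
    }
    ok <- S4Vectors::mcols(regions$regions)$usable
    counts_list <- regions$counts[ok]
    g <- S4Vectors::mcols(regions$regions)$g_noncoding[ok]
  } else {
    counts_list <- lapply(regions, .as_counts)
    if (is.null(g) || length(g) != length(counts_list)) {
      stop("supply one g per region")
    }
  }
  keep <- vapply(counts_list, function(x) x$L > 0, logical(1))
  counts_list <- counts_list[keep]; g <- g[keep]
  if (length(counts_list) == 0L) stop("no usable regions with codons")
  if (is.null(aa_freqs)) {
    aa_freqs <- aa_frequencies(counts_list)
  } else {
    aa_freqs <- .check_aa_freqs(aa_freqs)
  }
  d <- vapply(seq_along(counts_list), function(r) {
    suppressWarnings(
      .cais_core(counts_list[[r]], expected_usage(g[[r]]), aa_freqs, mode)$value)
  }, numeric(1))
  Lr <- vapply(counts_list, function(x) as.numeric(x$L), numeric(1))
  pos <- d > 0
  n_dropped <- sum(!pos)
  if (!any(pos)) stop("all regions dropped: no positive inner divergence")
  L <- sum(Lr[pos])
  value <- exp(sum(Lr[pos] * log(d[pos])) / L)
  structure(list(value = value, mode = "local_gc", inner_mode = mode,
                 region_divergence = d, region_L = Lr,
                 n_regions = length(d), n_dropped = n_dropped,
                 g_used = stats::weighted.mean(g, Lr), L = L,
                 per_family = NULL),
            class = "cais_result")
}

# ------------------------------------------------------------------- ENC

#' GC-corrected effective number of codons, stop codons included
#'
#' For each family with \eqn{n_a \ge 2} synonymous codons and \eqn{N_a \ge
#' 2} observations, the squared deviation of conditional usage from its GC
#' expectation is \eqn{X_a^2 = N_a \sum_{i \in a} (O_{i|a} -
#' E_{i|a})^2 / E_{i|a}}, giving the corrected homozygosity
#' \eqn{F'_a = (X_a^2 + N_a - n_a) / (n_a (N_a - 1))}. ENC sums the
#' reciprocals of the degeneracy-class means of \eqn{F'}:
#' \deqn{ENC = 2 + 9/\bar{F'}_2 + 2/\bar{F'}_3 + 5/\bar{F'}_4 +
#' 3/\bar{F'}_6,}
#' where the three-fold coefficient is 2 (not the classic 1) because the
#' stop codons join Ile as a second three-fold family, and the constant 2
#' counts the single-codon families Met and Trp. Range 21 (one codon per
#' family) to 64 (usage at GC expectation), up to finite-sample noise.
#'
#' @param cv \code{\link{codon_counts}} (or named count vector).
#' @param g Genomic GC content in (0, 1), or a \code{gc_composition} or
#'   \code{expected_usage}.
#' @return Object of class \code{"enc_result"}: \code{enc}, \code{chi2}
#'   (\eqn{X_a^2}), \code{f_corrected} (\eqn{F'_a}; NA for excluded
#'   families), \code{class_means}, \code{low_confidence} (TRUE when some
#'   degeneracy class had no eligible family and its mean was imputed at
#'   the null expectation \eqn{1/n_a}).
#' @export
enc <- function(cv, g) {
  cv <- .as_counts(cv)
  if (cv$L == 0L) stop("ENC undefined: no codons counted (L = 0)")
  eu <- if (inherits(g, "expected_usage")) g else expected_usage(g)
  usage <- codon_usage(cv)
  tab <- codon_table()
  fams <- unique(tab[, c("family", "n_a")])
  chi2 <- stats::setNames(rep(NA_real_, nrow(fams)), fams$family)
  fprime <- chi2
  for (k in seq_len(nrow(fams))) {
    a <- fams$family[k]; na <- fams$n_a[k]
    if (na < 2L) next
    Na <- cv$family_totals[[a]]
    idx <- which(tab$family == a)
    if (Na >= 1L) {
      O <- usage$conditional[idx]; E <- eu$E[idx]
      chi2[[a]] <- Na * sum((O - E)^2 / E)
    }
    if (Na >= 2L) {
      fprime[[a]] <- (chi2[[a]] + Na - na) / (na * (Na - 1))
    }
  }
  class_of <- stats::setNames(fams$n_a, fams$family)
  low_confidence <- FALSE
  class_means <- stats::setNames(numeric(4), c("2", "3", "4", "6"))
  for (cl in c(2, 3, 4, 6)) {
    vals <- fprime[names(class_of)[class_of == cl]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      class_means[[as.character(cl)]] <- 1 / cl  # null expectation fallback
      low_confidence <- TRUE
    } else {
      class_means[[as.character(cl)]] <- mean(vals)
    }
  }
  value <- 2 + 9 / class_means[["2"]] + 2 / class_means[["3"]] +
    5 / class_means[["4"]] + 3 / class_means[["6"]]
  structure(list(enc = value, chi2 = chi2, f_corrected = fprime,
                 class_means = class_means, low_confidence = low_confidence,
                 g_used = eu$g, L = cv$L),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("ENC = %.3f (g = %.4f, L = %s)%s\n", x$enc, x$g_used,
              format(x$L, big.mark = ","),
              if (x$low_confidence) " [low confidence: imputed class mean]" else ""))
  invisible(x)
}

# --------------------------------------------------------------- one-stop

#' Compute all codon adaptation metrics for one species
#'
#' @param cv \code{codon_counts} or named count vector.
#' @param g Genomic GC content.
#' @param aa_freqs Optional standardized amino-acid frequencies for CAIS.
#' @param cais_mode CAIS mode, \code{"standard"} or \code{"literal"}.
#' @return One-row data.frame: L, g, cai, cai_raw, cai_max, cais, enc.
#' @export
codon_metrics <- function(cv, g, aa_freqs = NULL,
                          cais_mode = c("standard", "literal")) {
  cais_mode <- match.arg(cais_mode)
  cv <- .as_counts(cv)
  eu <- if (inherits(g, "expected_usage")) g else expected_usage(g)
  ca <- rscu_cai(cv)
  cs <- cais(cv, eu, aa_freqs = aa_freqs, mode = cais_mode)
  en <- enc(cv, eu)
  data.frame(L = cv$L, g = eu$g, cai = ca$cai, cai_raw = ca$cai_raw,
             cai_max = ca$cai_max, cais = cs$value, enc = en$enc)
}
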