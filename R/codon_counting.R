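# Codon counting from CDS sequences, with QC.

#' Read coding sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA of coding sequences, one record per
#'   CDS.
#' @return A \code{Biostrings::DNAStringSet}.
#' @export
read_cds <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' QC policy for codon counting
#'
#' Defaults drop records whose length is not a multiple of 3, records
#' containing ambiguous bases, and records with an in-frame stop before the
#' final codon; records lacking a terminal stop are retained with a warning
#' flag. All policies can be switched off.
#'
#' @param drop_partial Drop records whose length is not divisible by 3.
#' @param drop_ambiguous Drop records containing non-ACGT characters.
#' @param drop_internal_stop Drop records with an in-frame stop codon before
#'   the last codon.
#' @param warn_no_terminal_stop Emit a warning flag when a retained record
#'   does not end in a stop codon.
#' @return A list of class \code{"qc_policy"}.
#' @export
qc_policy <- function(drop_partial = TRUE, drop_ambiguous = TRUE,
                      drop_internal_stop = TRUE,
                      warn_no_terminal_stop = TRUE) {
  structure(list(drop_partial = drop_partial,
                 drop_ambiguous = drop_ambiguous,
                 drop_internal_stop = drop_internal_stop,
                 warn_no_terminal_stop = warn_no_terminal_stop),
            class = "qc_policy")
}

.as_char_seqs <- function(x) {
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be a character vector or DNAStringSet")
  toupper(x)
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Count codon usage over a set of coding sequences
#'
#' Counts every codon of every retained record, including the initial ATG
#' and the terminal stop codon. Records are screened in order: length,
#' ambiguity, internal stop; only the first failure is reported per record.
#'
#' @param seqs Character vector or \code{DNAStringSet} of CDS nucleotide
#'   sequences (DNA alphabet; case-insensitive).
#' @param qc A \code{\link{qc_policy}}.
#' @return Object of class \code{"codon_counts"}: a list with \code{counts}
#'   (named integer vector over the 64 codons), \code{family_totals}
#'   (\eqn{N_a} per family), \code{L} (total codons counted) and \code{qc}
#'   (a QC report list).
#' @examples
#' count_codons(c("ATGAAATAA"))
#' @export
count_codons <- function(seqs, qc = qc_policy()) {
  seqs <- .as_char_seqs(seqs)
  n_in <- length(seqs)
  qc_rep <- list(n_records_in = n_in, n_records_kept = 0L,
                 n_dropped_length = 0L, n_dropped_internal_stop = 0L,
                 n_dropped_ambiguous = 0L, n_missing_terminal_stop = 0L,
                 empty_input = n_in == 0L)
  if (n_in == 0L) {
    warning("empty input: returning empty counts")
  }
  stops <- c("TAA", "TAG", "TGA")
  kept_codons <- vector("list", n_in)
  for (k in seq_len(n_in)) {
    s <- seqs[[k]]
    if (nchar(s) %% 3L != 0L) {
      if (qc$drop_partial) {
        qc_rep$n_dropped_length <- qc_rep$n_dropped_length + 1L
        next
      }
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
    if (grepl("[^ACGT]", s)) {
      if (qc$drop_ambiguous) {
        qc_rep$n_dropped_ambiguous <- qc_rep$n_dropped_ambiguous + 1L
        next
      }
    }
    cod <- .split_codons(s)
    if (grepl("[^ACGT]", s)) cod <- cod[!grepl("[^ACGT]", cod)]
    nc <- length(cod)
    if (nc == 0L) next
    if (qc$drop_internal_stop && nc > 1L && any(cod[-nc] %in% stops)) {
      qc_rep$n_dropped_internal_stop <- qc_rep$n_dropped_internal_stop + 1L
      next
    }
    if (qc$warn_no_terminal_stop && !(cod[nc] %in% stops)) {
      qc_rep$n_missing_terminal_stop <- qc_rep$n_missing_terminal_stop + 1L
    }
    qc_rep$n_records_kept <- qc_rep$n_records_kept + 1L
    kept_codons[[k]] <- cod
  }
  all_cod <- unlist(kept_codons, use.names = FALSE)
  counts <- table(factor(all_cod, levels = codons()))
  counts <- stats::setNames(as.integer(counts), codons())
  codon_counts(counts, qc = qc_rep)
}

#' Construct a codon_counts object from a named count vector
#'
#' @param counts Named non-negative numeric vector; names are codons. Codons
#'   absent from \code{counts} are taken as zero. Fractional values are
#'   allowed (useful for constructing analytic usage profiles); counting
#'   from sequences always yields integers.
#' @param qc Optional QC report list.
#' @return Object of class \code{"codon_counts"}.
#' @export
codon_counts <- function(counts, qc = NULL) {
  full <- stats::setNames(numeric(64L), codons())
  if (is.null(names(counts))) stop("counts must be named by codon")
  nm <- toupper(names(counts))
  if (any(!nm %in% codons())) {
    stop("unknown codon name(s): ",
         paste(setdiff(nm, codons()), collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  full[nm] <- as.numeric(counts)
  tab <- codon_table()
  fam_tot <- tapply(full[tab$codon], tab$family, sum)
  fam_tot <- stats::setNames(as.numeric(fam_tot), names(fam_tot))
  structure(list(counts = full,
                 family_totals = fam_tot[families()],
                 L = sum(full),
                 qc = qc),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts: L =", x$L, "codons,",
      sum(x$family_totals > 0), "of 21 families observed\n")
  if (!is.null(x$qc)) {
    cat(sprintf("  QC: %d/%d records kept (%d length, %d ambiguous, %d internal-stop dropped)\n",
                x$qc$n_records_kept, x$qc$n_records_in,
                x$qc$n_dropped_length, x$qc$n_dropped_ambiguous,
                x$qc$n_dropped_internal_stop))
  }
  invisible(x)
}

#' Observed codon usage distributions from counts
#'
#' @param cv A \code{\link{codon_counts}} object with \code{L > 0}.
#' @return Object of class \code{"codon_usage"}: \code{global} (\eqn{O_i =
#'   N_i/L}), \code{conditional} (\eqn{O_{i|a} = N_i/N_a}; \code{NA} for
#'   codons of families never observed), \code{family_freq} (\eqn{P_a =
#'   N_a/L}) and \code{L}.
#' @export
codon_usage <- function(cv) {
  stopifnot(inherits(cv, "codon_counts"))
  if (cv$L == 0L) stop("undefined distribution: no codons counted (L = 0)")
  tab <- codon_table()
  global <- cv$counts / cv$L
  fam_tot <- cv$family_totals[tab$family]
  conditional <- ifelse(fam_tot > 0, cv$counts / fam_tot, NA_real_)
  names(conditional) <- names(cv$counts)
  structure(list(global = global,
                 conditional = conditional,
                 family_freq = cv$family_totals / cv$L,
                 L = cv$L),
            class = "codon_usage")
}

#' Write codon counts as a TSV
#'
#' @param cv A \code{codon_counts} object or named list of them (one per
#'   species).
#' @param path Output TSV path; one row per codon, one count column per
#'   species.
#' @export
write_codon_counts <- function(cv, path) {
  if (inherits(cv, "codon_counts")) cv <- list(counts = cv)
  mat <- vapply(cv, function(x) x$counts, numeric(64L))
  df <- data.frame(codon = codons(), family = codon_table()$family, mat,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
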