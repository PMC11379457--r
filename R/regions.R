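# Local-GC region construction: merged CDS catchment areas and their
# non-coding GC content.
#
# Each annotated CDS interval is extended by `flank` bases on both sides
# (clamped at sequence ends); overlapping catchments -- whether from the
# same gene or different genes -- are merged into one region, so CDS of the
# same gene further apart than 2*flank end up in different regions. A
# region's GC content is computed from all its non-CDS sites (introns,
# UTRs, promoters, intergenic). Coordinates follow GRanges conventions
# (1-based, closed); GFF3 input already matches.

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a FASTA path or DNAStringSet")
  }
  genome
}

.as_cds_granges <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L &&
      file.exists(annotation)) {
    annotation <- rtracklayer::import(annotation)
  }
  if (!methods::is(annotation, "GRanges")) {
    stop("annotation must be a GFF3 path or a GRanges of CDS intervals")
  }
  if (!is.null(annotation$type)) {
    annotation <- annotation[as.character(annotation$type) == "CDS"]
  }
  if (length(annotation) == 0L) stop("annotation contains no CDS intervals")
  annotation
}

.cds_group_id <- function(cds) {
  mc <- S4Vectors::mcols(cds)
  for (col in c("Parent", "ID", "protein_id", "transcript_id", "gene_id",
                "Name")) {
    if (col %in% colnames(mc)) {
      v <- mc[[col]]
      if (methods::is(v, "List") || is.list(v)) {
        v <- vapply(v, function(z) if (length(z)) as.character(z[[1]]) else NA_character_,
                    character(1))
      }
      v <- as.character(v)
      if (!all(is.na(v))) return(v)
    }
  }
  as.character(seq_along(cds))
}

#' Build merged CDS-catchment regions with local non-coding GC
#'
#' @param genome Genome FASTA path or named \code{DNAStringSet}.
#' @param annotation GFF3 path or \code{GRanges}; rows with
#'   \code{type == "CDS"} are used.
#' @param cds_seqs Optional CDS sequences (\code{DNAStringSet} or named
#'   character) whose names match a CDS grouping attribute in the annotation
#'   (\code{Parent}, \code{ID}, \code{protein_id}, ...); when supplied, each
#'   region carries the codon counts of its CDS records, enabling local-GC
#'   CAIS. Without them, regions carry only annotation-based codon totals.
#' @param flank Catchment flank in bases on each side of every CDS interval
#'   (default 1500, i.e. CDS more than 3000 bp apart fall in different
#'   regions).
#' @param qc QC policy for counting codons of \code{cds_seqs}.
#' @return Object of class \code{"gc_regions"}: list with \code{regions}
#'   (a \code{GRanges} with metadata columns \code{n_cds},
#'   \code{noncoding_sites}, \code{g_noncoding}, \code{n_codons},
#'   \code{usable}) and \code{counts} (per-region \code{codon_counts}, or
#'   \code{NULL}).
#' @export
build_regions <- function(genome, annotation, cds_seqs = NULL, flank = 1500L,
                          qc = qc_policy()) {
  genome <- .as_genome(genome)
  cds <- .as_cds_granges(annotation)
  seqlen <- stats::setNames(Biostrings::width(genome), names(genome))
  sn <- as.character(GenomicRanges::seqnames(cds))
  if (any(!sn %in% names(seqlen))) {
    stop("CDS on sequences absent from the genome: ",
         paste(unique(sn[!sn %in% names(seqlen)]), collapse = ", "))
  }
  if (any(GenomicRanges::start(cds) < 1L) ||
      any(GenomicRanges::end(cds) > seqlen[sn])) {
    stop("CDS interval outside sequence bounds")
  }
  catch <- GenomicRanges::GRanges(
    seqnames = sn,
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(cds) - as.integer(flank)),
      end = pmin(seqlen[sn], GenomicRanges::end(cds) + as.integer(flank))
    )
  )
  regions <- GenomicRanges::reduce(GenomicRanges::sort(catch))
  cds_union <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = sn, ranges = IRanges::ranges(cds)))

  hits <- GenomicRanges::findOverlaps(GenomicRanges::GRanges(
    seqnames = sn, ranges = IRanges::ranges(cds)), regions, type = "within")
  cds_region <- rep(NA_integer_, length(cds))
  cds_region[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

  n_reg <- length(regions)
  n_cds <- tabulate(cds_region, nbins = n_reg)
  noncoding_sites <- integer(n_reg)
  g_noncoding <- rep(NA_real_, n_reg)
  for (r in seq_len(n_reg)) {
    nc <- GenomicRanges::setdiff(regions[r], cds_union)
    if (length(nc) == 0L) next
    chr <- as.character(GenomicRanges::seqnames(nc))[1]
    views <- Biostrings::extractAt(genome[[chr]], IRanges::ranges(nc))
    freq <- colSums(Biostrings::letterFrequency(views, c("A", "C", "G", "T")))
    n <- sum(freq)
    noncoding_sites[r] <- n
    if (n > 0) g_noncoding[r] <- (freq[["G"]] + freq[["C"]]) / n
  }

  counts <- NULL
  if (!is.null(cds_seqs)) {
    cds_seqs <- .as_char_seqs(cds_seqs)
    if (is.null(names(cds_seqs))) stop("cds_seqs must be named")
    ids <- .cds_group_id(cds)
    rec_region <- vapply(names(cds_seqs), function(nm) {
      idx <- which(ids == nm)
      if (length(idx) == 0L) return(NA_integer_)
      # a record spanning several regions is assigned where most of it lies
      regs <- cds_region[idx]
      w <- tapply(GenomicRanges::width(cds)[idx], regs, sum)
      as.integer(names(w)[which.max(w)])
    }, integer(1))
    if (any(is.na(rec_region))) {
      warning(sum(is.na(rec_region)),
              " CDS record(s) not matched to an annotation id; skipped")
    }
    counts <- lapply(seq_len(n_reg), function(r) {
      recs <- cds_seqs[!is.na(rec_region) & rec_region == r]
      if (length(recs) == 0L) return(codon_counts(stats::setNames(integer(0), character(0))))
      count_codons(recs, qc = qc)
    })
    n_codons <- vapply(counts, function(x) x$L, numeric(1))
  } else {
    w <- tapply(GenomicRanges::width(cds), cds_region, sum)
    n_codons <- numeric(n_reg)
    n_codons[as.integer(names(w))] <- as.numeric(w) / 3
  }

  usable <- noncoding_sites > 0L & !is.na(g_noncoding) &
    g_noncoding > 0 & g_noncoding < 1
  S4Vectors::mcols(regions)$n_cds <- n_cds
  S4Vectors::mcols(regions)$noncoding_sites <- noncoding_sites
  S4Vectors::mcols(regions)$g_noncoding <- g_noncoding
  S4Vectors::mcols(regions)$n_codons <- n_codons
  S4Vectors::mcols(regions)$usable <- usable
  structure(list(regions = regions, counts = counts), class = "gc_regions")
}

#' @export
print.gc_regions <- function(x, ...) {
  r <- x$regions
  cat(sprintf("%d merged CDS-catchment region(s); %d usable for local GC\n",
              length(r), sum(r$usable)))
  cat(sprintf("  non-coding GC range: %.3f - %.3f\n",
              min(r$g_noncoding, na.rm = TRUE),
              max(r$g_noncoding, na.rm = TRUE)))
  invisible(x)
}

#' GC heterogeneity of a genome's regions
#'
#' Codon-count-weighted mean absolute deviation of regional non-coding GC
#' from genome-wide GC. High values would be expected if GC-biased gene
#' conversion, rather than selection on codon usage, drove codon adaptation
#' scores.
#'
#' @param regions A \code{gc_regions} object (or a data.frame/list with
#'   numeric \code{g_noncoding}, \code{n_codons}, logical \code{usable}).
#' @param global_g Genome-wide GC content (number or
#'   \code{gc_composition}).
#' @param method \code{"mean_abs_dev"} (default): weighted mean of
#'   \eqn{|g_r - g|}; \code{"abs_mean_dev"}: absolute deviation of the
#'   weighted mean \eqn{|\bar{g_r} - g|}.
#' @return Non-negative scalar.
#' @export
gc_heterogeneity <- function(regions, global_g,
                             method = c("mean_abs_dev", "abs_mean_dev")) {
  method <- match.arg(method)
  g <- .as_g(global_g)
  if (inherits(regions, "gc_regions")) {
    mc <- S4Vectors::mcols(regions$regions)
    gr <- mc$g_noncoding; w <- mc$n_codons; ok <- mc$usable
  } else {
    gr <- regions$g_noncoding; w <- regions$n_codons
    ok <- if (!is.null(regions$usable)) regions$usable else rep(TRUE, length(gr))
  }
  ok <- ok & w > 0
  if (!any(ok)) stop("no usable regions with codons")
  gr <- gr[ok]; w <- w[ok]
  if (method == "mean_abs_dev") {
    sum(w * abs(gr - g)) / sum(w)
  } else {
    abs(sum(w * gr) / sum(w) - g)
  }
}

#' Write regions as a BED-like TSV
#'
#' @param x A \code{gc_regions} object.
#' @param path Output TSV path (columns: seqid, start, end in 0-based
#'   half-open BED convention, n_cds, g_noncoding, n_codons, usable).
#' @export
write_regions <- function(x, path) {
  stopifnot(inherits(x, "gc_regions"))
  r <- x$regions
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(r)),
                   start = GenomicRanges::start(r) - 1L,
                   end = GenomicRanges::end(r),
                   n_cds = r$n_cds,
                   g_noncoding = r$g_noncoding,
                   n_codons = r$n_codons,
                   usable = r$usable)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
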