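# All genomic coordinates in this package are 0-based half-open [start, end)
# on an explicit strand; GTF/GFF3 I/O converts from/to 1-based inclusive.

#' Create a genomic interval
#'
#' Intervals are 0-based, half-open `[start, end)` with an explicit strand.
#'
#' @param chrom Chromosome / contig name.
#' @param start Integer start, 0-based inclusive.
#' @param end Integer end, exclusive; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (!is.character(chrom) || length(chrom) != 1L)
    stop("chrom must be a single string")
  if (is.na(start) || is.na(end) || start >= end)
    stop("invalid interval: require start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Create a transcript model
#'
#' Exons are stored in genomic order (sorted by start) regardless of strand;
#' transcript (5'->3') order is derived from the strand when needed. An
#' optional CDS is given as genomic sub-intervals of the exons.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   coordinates; must be non-overlapping.
#' @param cds_starts,cds_ends Optional CDS segment coordinates; every CDS
#'   segment must lie within the exon union.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_starts = NULL, cds_ends = NULL) {
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) == 0L) stop("transcript needs >= 1 exon")
  if (length(exon_starts) != length(exon_ends)) stop("exon start/end length mismatch")
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (any(exon_ends <= exon_starts)) stop("empty or inverted exon")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("overlapping exons in transcript ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  tx <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom), strand = strand,
    exon_starts = exon_starts, exon_ends = exon_ends,
    cds_starts = NULL, cds_ends = NULL
  ), class = "transcript_model")
  if (!is.null(cds_starts) && length(cds_starts) > 0L) {
    cds_starts <- as.integer(cds_starts); cds_ends <- as.integer(cds_ends)
    o <- order(cds_starts)
    cds_starts <- cds_starts[o]; cds_ends <- cds_ends[o]
    ok <- vapply(seq_along(cds_starts), function(i) {
      any(exon_starts <= cds_starts[i] & exon_ends >= cds_ends[i])
    }, logical(1))
    if (!all(ok)) stop("CDS not contained in exon union for ", transcript_id)
    tx$cds_starts <- cds_starts; tx$cds_ends <- cds_ends
  }
  tx
}

#' Number of exons of a transcript
#' @param tx A `transcript_model`.
#' @return Integer exon count.
#' @export
n_exons <- function(tx) length(tx$exon_starts)

#' Total exonic (mature transcript) length
#' @param tx A `transcript_model`.
#' @return Integer length in nucleotides.
#' @export
transcript_length <- function(tx) sum(tx$exon_ends - tx$exon_starts)

#' Create a gene model
#'
#' @param gene_id Gene identifier; all transcripts must carry it and share
#'   one chromosome and strand.
#' @param transcripts List of `transcript_model` objects (>= 1).
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts) {
  if (length(transcripts) == 0L) stop("gene needs >= 1 transcript")
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  if (!all(gid == gene_id)) stop("transcript gene_id mismatch for ", gene_id)
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("transcripts of ", gene_id, " must share chrom and strand")
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = as.character(gene_id), chrom = chrom,
                 strand = strand, transcripts = transcripts),
            class = "gene_model")
}

#' Introns of a transcript
#'
#' One junction per adjacent exon pair, with length-bound flags checked
#' against the configured minimum and maximum intron sizes. Violations are
#' reported as flags, never as errors; filtering is the caller's policy.
#'
#' @param tx A `transcript_model`.
#' @param min_intron,max_intron Intron length bounds (defaults 20 and 8000).
#' @return A data.frame with columns `chrom`, `donor_end` (0-based intron
#'   start), `acceptor_start` (intron end, exclusive), `strand`, `length`,
#'   `below_min`, `above_max`. Zero rows for single-exon transcripts.
#' @export
introns_of <- function(tx, min_intron = 20L, max_intron = 8000L) {
  k <- n_exons(tx)
  if (k < 2L) {
    return(data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer(), strand = character(),
                      length = integer(), below_min = logical(),
                      above_max = logical()))
  }
  ds <- tx$exon_ends[-k]; as_ <- tx$exon_starts[-1L]
  len <- as_ - ds
  data.frame(chrom = tx$chrom, donor_end = ds, acceptor_start = as_,
             strand = tx$strand, length = len,
             below_min = len < min_intron, above_max = len > max_intron)
}

#' Map a genomic position to a transcript offset
#'
#' The offset is measured 5'->3' along the mature transcript (0-based), so
#' for minus-strand transcripts offset 0 is the genomically rightmost exonic
#' base.
#'
#' @param tx A `transcript_model`.
#' @param genomic_pos Integer vector of 0-based genomic positions; each must
#'   fall inside an exon.
#' @return Integer vector of transcript offsets.
#' @seealso [to_genomic_coords()] for the inverse.
#' @export
to_transcript_coords <- function(tx, genomic_pos) {
  vapply(as.integer(genomic_pos), function(p) {
    i <- which(tx$exon_starts <= p & p < tx$exon_ends)
    if (length(i) != 1L) stop("position ", p, " is not exonic in ",
                              tx$transcript_id)
    if (tx$strand == "+") {
      before <- if (i > 1L) sum(tx$exon_ends[seq_len(i - 1L)] -
                                tx$exon_starts[seq_len(i - 1L)]) else 0L
      before + (p - tx$exon_starts[i])
    } else {
      k <- n_exons(tx)
      after <- if (i < k) sum(tx$exon_ends[(i + 1L):k] -
                              tx$exon_starts[(i + 1L):k]) else 0L
      after + (tx$exon_ends[i] - 1L - p)
    }
  }, integer(1))
}

#' Map a transcript offset to its genomic position
#'
#' Inverse of [to_transcript_coords()].
#'
#' @param tx A `transcript_model`.
#' @param offset Integer vector of 0-based transcript offsets.
#' @return Integer vector of genomic positions.
#' @export
to_genomic_coords <- function(tx, offset) {
  L <- transcript_length(tx)
  vapply(as.integer(offset), function(off) {
    if (is.na(off) || off < 0L || off >= L)
      stop("offset ", off, " outside transcript ", tx$transcript_id)
    lens <- tx$exon_ends - tx$exon_starts
    if (tx$strand == "+") {
      cum <- cumsum(lens)
      i <- which(off < cum)[1L]
      prev <- if (i > 1L) cum[i - 1L] else 0L
      tx$exon_starts[i] + (off - prev)
    } else {
      k <- n_exons(tx)
      cum <- cumsum(rev(lens))          # transcript order = right to left
      j <- which(off < cum)[1L]
      prev <- if (j > 1L) cum[j - 1L] else 0L
      i <- k - j + 1L
      tx$exon_ends[i] - 1L - (off - prev)
    }
  }, integer(1))
}

#' Number of transcript bases 5' of a genomic boundary
#'
#' Counts the exonic bases of `tx` that lie strictly 5' (in transcript
#' orientation) of the genomic boundary `b`, where `b` is interpreted as the
#' gap between positions `b - 1` and `b`. Unlike [to_transcript_coords()],
#' `b` need not be exonic: for a boundary inside an intron the count equals
#' the offset of the first exonic base past the junction, so the same number
#' addresses an exon-exon junction in a spliced isoform and the matching
#' exon-intron boundary in an isoform that retains the intron.
#'
#' @param tx A `transcript_model`.
#' @param b Genomic boundary (0-based).
#' @return Integer count in `[0, transcript_length(tx)]`.
#' @export
transcript_bases_before <- function(tx, b) {
  b <- as.integer(b)
  if (tx$strand == "+") {
    sum(pmax(0L, pmin(tx$exon_ends, b) - tx$exon_starts))
  } else {
    sum(pmax(0L, tx$exon_ends - pmax(tx$exon_starts, b)))
  }
}

#' Exonic genomic interval set of a transcript's CDS, 5'UTR or 3'UTR
#' @param tx A `transcript_model` with a CDS.
#' @return List with integer matrix-like fields `starts`, `ends`.
#' @keywords internal
cds_region <- function(tx) {
  if (is.null(tx$cds_starts)) stop("transcript ", tx$transcript_id, " has no CDS")
  list(starts = tx$cds_starts, ends = tx$cds_ends)
}

#' Format helpers
#' @param x object
#' @param ... ignored
#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s), %d nt%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, n_exons(x),
              transcript_length(x),
              if (is.null(x$cds_starts)) "" else ", CDS"))
  invisible(x)
}

#' @rdname print.transcript_model
#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s %s:%s, %d transcript(s)>\n", x$gene_id, x$chrom,
              x$strand, length(x$transcripts)))
  invisible(x)
}
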