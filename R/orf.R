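# ORF prediction on mature transcript sequences, NMD rule calling, and
# domain-arrangement projection between isoforms of one gene.

#' Predict the ORF of a transcript sequence
#'
#' Scans the three forward reading frames for complete `ATG ... stop` spans.
#' Within a frame, one candidate is kept per stop codon: the span from the
#' 5'-most ATG following the previous stop (nested ATGs sharing a stop are
#' the same candidate). The longest candidate of at least `min_len_aa`
#' residues is returned. The verdict is `"none"` when there is no candidate
#' and `"ambiguous"` when two candidates tie in length, or when the
#' runner-up reaches `ambiguity_ratio` times the top length — transcripts
#' with no ORF or with ambiguous ORFs are conventionally excluded from
#' downstream analysis. The reverse strand is never scanned: mature
#' transcript sequences are already oriented 5'->3'.
#'
#' @param seq Transcript nucleotide string (ACGTN; U is accepted and
#'   treated as T).
#' @param min_len_aa Minimum protein length in residues (default 100,
#'   the common ORF-prediction convention).
#' @param ambiguity_ratio Runner-up/top length ratio at or above which the
#'   prediction is called ambiguous (default 1, i.e. exact ties only).
#' @return List with `verdict` (`"ok"`, `"none"` or `"ambiguous"`) and, for
#'   `"ok"`: `cds_start` (0-based transcript offset of the A of ATG),
#'   `cds_stop` (offset of the first base of the stop codon), `protein`
#'   (residue string without the stop), `n_candidates`.
#' @export
find_orf <- function(seq, min_len_aa = 100L, ambiguity_ratio = 1) {
  seq <- toupper(chartr("U", "T", seq))
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")
  starts <- integer(); stops <- integer()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    cod <- substring(seq, frame + 3L * (seq_len(ncod) - 1L) + 1L,
                     frame + 3L * seq_len(ncod))
    is_start <- cod == "ATG"
    is_stop <- cod %in% c("TAA", "TAG", "TGA")
    open <- NA_integer_
    for (i in seq_len(ncod)) {
      if (is.na(open) && is_start[i]) open <- i
      if (!is.na(open) && is_stop[i]) {
        starts <- c(starts, frame + 3L * (open - 1L))
        stops <- c(stops, frame + 3L * (i - 1L))
        open <- NA_integer_
      }
    }
  }
  if (length(starts) == 0L) return(list(verdict = "none"))
  len_aa <- (stops - starts) %/% 3L
  keep <- len_aa >= min_len_aa
  if (!any(keep)) return(list(verdict = "none"))
  starts <- starts[keep]; stops <- stops[keep]; len_aa <- len_aa[keep]
  o <- order(-len_aa, starts)
  n_cand <- length(starts)
  if (n_cand >= 2L) {
    top <- len_aa[o[1L]]; second <- len_aa[o[2L]]
    if (second >= ambiguity_ratio * top)
      return(list(verdict = "ambiguous", n_candidates = n_cand))
  }
  best <- o[1L]
  cds <- substr(seq, starts[best] + 1L, stops[best])
  prot <- translate_dna(cds)
  list(verdict = "ok", cds_start = starts[best], cds_stop = stops[best],
       protein = prot, n_candidates = n_cand)
}

#' Call the NMD rules on a transcript's ORF
#'
#' Two rules mark a transcript as an NMD candidate: (a) 3'UTR longer than
#' 350 nt; (b) the stop codon more than 55 nt upstream of the last exon-exon
#' junction. Distances are measured 5'->3' in transcript coordinates from
#' the first base of the stop codon.
#'
#' @param tx A `transcript_model`.
#' @param orf An ORF as returned by [find_orf()] (verdict `"ok"`), with
#'   offsets on `tx`'s mature sequence.
#' @param utr3_threshold,junction_threshold Rule thresholds in nt (defaults
#'   350 and 55; both strict inequalities).
#' @return List with `utr3_len`, `stop_to_last_junction` (negative when the
#'   stop codon lies in the last exon; `-Inf` for single-exon transcripts),
#'   `rule_long_utr3`, `rule_junction_distance`, `nmd_candidate`.
#' @export
nmd_call <- function(tx, orf, utr3_threshold = 350, junction_threshold = 55) {
  L <- transcript_length(tx)
  if (orf$cds_stop + 3L > L)
    stop("stop codon extends beyond transcript end")
  utr3_len <- L - orf$cds_stop - 3L
  k <- n_exons(tx)
  if (k < 2L) {
    d <- -Inf
  } else {
    lens <- tx$exon_ends - tx$exon_starts
    if (tx$strand == "-") lens <- rev(lens)
    last_junction <- sum(lens[-k])     # offset of first base after junction
    d <- last_junction - orf$cds_stop
  }
  rule_a <- utr3_len > utr3_threshold
  rule_b <- is.finite(d) && d > junction_threshold
  list(transcript_id = tx$transcript_id, utr3_len = utr3_len,
       stop_to_last_junction = d, rule_long_utr3 = rule_a,
       rule_junction_distance = rule_b, nmd_candidate = rule_a || rule_b)
}

#' Project a primary isoform's domain arrangement onto a variant isoform
#'
#' Each domain's codons are mapped from primary-protein coordinates through
#' the primary transcript to genomic positions, looked up in the variant,
#' and checked for in-frame presence in the variant CDS. A codon is
#' retained in frame when all three of its bases are exonic in the variant,
#' map to three consecutive variant CDS positions (in transcript order),
#' and start on a variant codon boundary. Domains with every codon in
#' frame are `retained`; those with at least `lost_below` of their codons
#' in frame are `truncated`; the rest (including frame-shifted domains) are
#' `lost`.
#'
#' @param primary_tx,variant_tx `transcript_model`s of one gene.
#' @param primary_orf,variant_orf [find_orf()] results for the two mature
#'   sequences.
#' @param domains Data.frame with `name`, `start_aa`, `end_aa` (1-based,
#'   inclusive, primary-protein coordinates).
#' @param lost_below Retained-codon fraction below which a partially
#'   present domain is called `lost` rather than `truncated` (default 0.5).
#' @return Data.frame `name`, `start_aa`, `end_aa`, `codons_in_frame`,
#'   `status` in `retained`/`truncated`/`lost`.
#' @export
project_domains <- function(primary_tx, primary_orf, variant_tx, variant_orf,
                            domains, lost_below = 0.5) {
  prot_len <- nchar(primary_orf$protein)
  v_cds_start <- variant_orf$cds_start
  v_cds_stop <- variant_orf$cds_stop
  out <- domains
  out$codons_in_frame <- NA_real_
  out$status <- NA_character_
  for (i in seq_len(nrow(domains))) {
    s_aa <- domains$start_aa[i]; e_aa <- domains$end_aa[i]
    if (s_aa < 1L || e_aa > prot_len || s_aa > e_aa)
      stop("domain ", domains$name[i], " outside the primary protein")
    n_cod <- e_aa - s_aa + 1L
    in_frame <- 0L
    for (codon in s_aa:e_aa) {
      tx_nt <- primary_orf$cds_start + 3L * (codon - 1L) + 0:2
      gpos <- to_genomic_coords(primary_tx, tx_nt)
      if (!all(exonic_at(variant_tx, gpos))) next
      v_off <- to_transcript_coords(variant_tx, gpos)
      v_off <- sort(v_off)
      if (v_off[2L] != v_off[1L] + 1L || v_off[3L] != v_off[2L] + 1L) next
      if (v_off[1L] < v_cds_start || v_off[3L] >= v_cds_stop) next
      if ((v_off[1L] - v_cds_start) %% 3L != 0L) next
      in_frame <- in_frame + 1L
    }
    frac <- in_frame / n_cod
    out$codons_in_frame[i] <- frac
    out$status[i] <- if (frac == 1) "retained"
                     else if (frac >= lost_below) "truncated" else "lost"
  }
  out
}

#' Screen a gene for AS isoforms with putative novel function
#'
#' A variant is flagged when (a) it retains at least one conserved domain
#' and (b) its `(name, status)` domain arrangement differs from the
#' primary's — e.g. a transcription-factor isoform that keeps its
#' dimerization domain but loses its DNA-binding region.
#'
#' @param primary_arrangement Data.frame as from [project_domains()] for
#'   the primary isoform (all `retained` by construction).
#' @param variant_arrangements Named list of such data.frames, one per
#'   variant isoform.
#' @return List with `flagged` (overall) and `report` data.frame per
#'   variant (`transcript_id`, `n_retained`, `arrangement_differs`,
#'   `novel_candidate`).
#' @export
novel_isoform_screen <- function(primary_arrangement, variant_arrangements) {
  key <- function(arr) paste(arr$name, arr$status, collapse = ";")
  primary_key <- key(primary_arrangement)
  rows <- lapply(names(variant_arrangements), function(id) {
    arr <- variant_arrangements[[id]]
    n_ret <- sum(arr$status == "retained")
    differs <- key(arr) != primary_key
    data.frame(transcript_id = id, n_retained = n_ret,
               arrangement_differs = differs,
               novel_candidate = n_ret >= 1L && differs,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(flagged = any(report$novel_candidate), report = report)
}
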