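# Protein-level validation of AS isoforms from a peptide table: confidence
# filtering, unique gene mapping, and junction-spanning evidence.

#' Tryptic digestion of a protein
#'
#' Cleaves after K or R, except when the next residue is P.
#'
#' @param protein Amino-acid string.
#' @return Character vector of peptides in N->C order.
#' @export
tryptic_digest <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n == 0L) return(character())
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds)
  vapply(seq_len(length(bounds) - 1L), function(i)
    paste(aa[(bounds[i] + 1L):bounds[i + 1L]], collapse = ""), "")
}

#' Confidence filter for peptide records
#'
#' @param records Data.frame with `sequence` and `confidence` in `[0, 1]`.
#' @param min_conf Minimum retained confidence (default 0.95; the boundary
#'   value is retained).
#' @return The retained subset of `records`.
#' @export
filter_peptides <- function(records, min_conf = 0.95) {
  if (any(records$confidence < 0 | records$confidence > 1))
    stop("confidence outside [0, 1]")
  records[records$confidence >= min_conf, , drop = FALSE]
}

#' Map peptides onto a proteome
#'
#' Exact substring matching of each peptide against every protein. Peptides
#' matching proteins of two or more genes are discarded and reported as
#' ambiguous; matches across isoforms of a single gene are kept.
#'
#' @param records Peptide data.frame (`sequence`, `confidence`).
#' @param proteome Data.frame with `transcript_id`, `gene_id`, `protein`.
#' @param il_equivalent Treat I and L as identical (default `FALSE`; exact
#'   matching is the strictest reading).
#' @return List with `supports` data.frame (`sequence`, `confidence`,
#'   `gene_id`, `transcript_id`, `aa_start`, `aa_end`, 1-based inclusive
#'   protein coordinates) and `ambiguous` (character vector of discarded
#'   peptide sequences).
#' @export
map_peptides <- function(records, proteome, il_equivalent = FALSE) {
  xform <- function(s) if (il_equivalent) chartr("I", "L", s) else s
  prot <- xform(proteome$protein)
  rows <- list(); ambiguous <- character()
  for (r in seq_len(nrow(records))) {
    pep <- records$sequence[r]
    q <- xform(pep)
    hit_tx <- integer(); hit_pos <- integer()
    for (p in which(grepl(q, prot, fixed = TRUE))) {
      m <- gregexpr(q, prot[p], fixed = TRUE)[[1]]
      hit_tx <- c(hit_tx, rep(p, length(m)))
      hit_pos <- c(hit_pos, as.integer(m))
    }
    if (!length(hit_tx)) next
    genes_hit <- unique(proteome$gene_id[hit_tx])
    if (length(genes_hit) >= 2L) {
      ambiguous <- c(ambiguous, pep)
      next
    }
    for (i in seq_along(hit_tx)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, confidence = records$confidence[r],
        gene_id = proteome$gene_id[hit_tx[i]],
        transcript_id = proteome$transcript_id[hit_tx[i]],
        aa_start = hit_pos[i], aa_end = hit_pos[i] + nchar(pep) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  supports <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), confidence = numeric(),
               gene_id = character(), transcript_id = character(),
               aa_start = integer(), aa_end = integer(),
               stringsAsFactors = FALSE)
  list(supports = supports, ambiguous = unique(ambiguous))
}

#' Junction-spanning peptide evidence for AS events
#'
#' A mapped peptide validates an AS event on an isoform when its protein
#' interval, mapped through the isoform's CDS to transcript coordinates,
#' covers a boundary of the event's alternative region with at least
#' `min_overhang` complete residues on each side. The boundary position in
#' an isoform is the count of that isoform's transcript bases 5' of the
#' genomic boundary, so the same definition covers the exon-exon junction
#' of the isoform that splices the region out and the exon-intron boundary
#' of the isoform that retains it.
#'
#' @param supports Mapped peptides (from [map_peptides()]).
#' @param genes Named list of `gene_model`s.
#' @param orfs Named list of [find_orf()] results keyed by transcript_id.
#' @param events Events data.frame (from [classify_gene()] over the genes).
#' @param min_overhang Minimum complete residues on each side of the
#'   junction (default 1).
#' @return Data.frame with one row per validation: `gene_id`, `type`,
#'   `region`, `transcript_id`, `sequence`, `boundary`, `overhang_5`,
#'   `overhang_3`.
#' @export
junction_evidence <- function(supports, genes, orfs, events,
                              min_overhang = 1L) {
  out <- list()
  for (r in seq_len(nrow(supports))) {
    tid <- supports$transcript_id[r]
    gid <- supports$gene_id[r]
    orf <- orfs[[tid]]
    if (is.null(orf) || orf$verdict != "ok") next
    tx <- genes[[gid]]$transcripts[[tid]]
    nt_start <- orf$cds_start + 3L * (supports$aa_start[r] - 1L)
    nt_end <- orf$cds_start + 3L * supports$aa_end[r]
    ev <- events[events$gene_id == gid, , drop = FALSE]
    for (e in seq_len(nrow(ev))) {
      reg <- parse_region(ev$region[e])
      for (b in unique(c(reg$starts, reg$ends))) {
        t <- transcript_bases_before(tx, b)
        n5 <- min((t - nt_start) %/% 3L, supports$aa_end[r] -
                    supports$aa_start[r] + 1L)
        n3 <- min((nt_end - t) %/% 3L, supports$aa_end[r] -
                    supports$aa_start[r] + 1L)
        if (n5 >= min_overhang && n3 >= min_overhang) {
          out[[length(out) + 1L]] <- data.frame(
            gene_id = gid, type = ev$type[e], region = ev$region[e],
            transcript_id = tid, sequence = supports$sequence[r],
            boundary = b, overhang_5 = n5, overhang_3 = n3,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), type = character(),
                      region = character(), transcript_id = character(),
                      sequence = character(), boundary = integer(),
                      overhang_5 = integer(), overhang_3 = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Run the three peptide-evidence criteria as one filter chain
#'
#' Confidence filter, unique-gene mapping, then junction-spanning evidence.
#'
#' @inheritParams junction_evidence
#' @param records Raw peptide records (`sequence`, `confidence`).
#' @param proteome Data.frame with `transcript_id`, `gene_id`, `protein`.
#' @param min_conf Confidence threshold (default 0.95).
#' @return List with `validated` (junction evidence data.frame),
#'   `supports`, `ambiguous`, `n_input`, `n_confident`.
#' @export
validate_isoforms <- function(records, proteome, genes, orfs, events,
                              min_conf = 0.95, min_overhang = 1L) {
  confident <- filter_peptides(records, min_conf)
  mapped <- map_peptides(confident, proteome)
  validated <- junction_evidence(mapped$supports, genes, orfs, events,
                                 min_overhang)
  list(validated = validated, supports = mapped$supports,
       ambiguous = mapped$ambiguous, n_input = nrow(records),
       n_confident = nrow(confident))
}
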