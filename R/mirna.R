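# miRNA target-site scanning with a transparent complementarity-penalty
# score, and classification of AS-coupled miRNA regulation (target sites
# gained or lost between isoforms of one gene).

#' Scanner configuration
#'
#' The expectation score of an aligned site is the sum of per-position
#' penalties of the miRNA/target duplex: 0 for a Watson-Crick pair, 0.5 for
#' a G:U wobble, 1 for a mismatch; gaps are not allowed. Penalties are
#' doubled inside the seed (miRNA positions 2-13, 5'->3'). Sites are
#' reported when the total is at or below the cutoff.
#'
#' @param mismatch,wobble Per-position penalties (defaults 1 and 0.5).
#' @param seed_from,seed_to Seed positions on the miRNA (defaults 2 and 13).
#' @param seed_multiplier Penalty weight inside the seed (default 2).
#' @param cutoff Maximum reported expectation (default 5).
#' @return A list of class `mirna_config`.
#' @export
mirna_config <- function(mismatch = 1, wobble = 0.5, seed_from = 2L,
                         seed_to = 13L, seed_multiplier = 2, cutoff = 5) {
  structure(list(mismatch = mismatch, wobble = wobble,
                 seed_from = as.integer(seed_from),
                 seed_to = as.integer(seed_to),
                 seed_multiplier = seed_multiplier, cutoff = cutoff),
            class = "mirna_config")
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Scan a transcript for miRNA target sites
#'
#' The reversed miRNA is slid along the transcript so that miRNA position 1
#' (5' end) pairs with the 3'-most base of each candidate site. Overlapping
#' hits of one miRNA are resolved to the lowest-penalty site; ties go to
#' the 5'-most site on the transcript.
#'
#' @param tx_seq Mature transcript sequence (DNA or RNA alphabet).
#' @param mirnas Named character vector of mature miRNA sequences (RNA,
#'   19-24 nt).
#' @param cfg A [mirna_config()].
#' @param transcript_id Optional id recorded in the result.
#' @return Data.frame with `transcript_id`, `mirna_id`, `start`, `end`
#'   (0-based half-open transcript offsets), `expectation`.
#' @export
scan_targets <- function(tx_seq, mirnas, cfg = mirna_config(),
                         transcript_id = NA_character_) {
  target <- toupper(chartr("T", "U", tx_seq))
  tvec <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(tvec)
  out <- list()
  for (mid in names(mirnas)) {
    m <- strsplit(toupper(mirnas[[mid]]), "", fixed = TRUE)[[1]]
    n <- length(m)
    if (n < 19L || n > 24L) stop("miRNA ", mid, " length out of range 19-24")
    if (any(!m %in% names(RNA_COMPLEMENT)))
      stop("miRNA ", mid, " has non-ACGU characters")
    nwin <- L - n + 1L
    if (nwin < 1L) next
    pen <- numeric(nwin)
    for (j in seq_len(n)) {
      w <- if (j >= cfg$seed_from && j <= cfg$seed_to)
        cfg$seed_multiplier else 1
      tpos <- seq_len(nwin) + (n - j)   # antiparallel pairing
      tb <- tvec[tpos]
      mb <- m[j]
      p <- ifelse(tb == RNA_COMPLEMENT[[mb]], 0,
                  ifelse((mb == "G" & tb == "U") | (mb == "U" & tb == "G"),
                         cfg$wobble, cfg$mismatch))
      pen <- pen + w * p
    }
    hits <- which(pen <= cfg$cutoff)
    # resolve overlapping hits: lowest penalty, then 5'-most
    while (length(hits)) {
      best <- hits[order(pen[hits], hits)][1L]
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = transcript_id, mirna_id = mid,
        start = best - 1L, end = best - 1L + n,
        expectation = pen[best], stringsAsFactors = FALSE)
      hits <- hits[hits <= best - n | hits >= best + n]
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), mirna_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan every isoform of a gene set
#'
#' @param genes Named list of `gene_model`s.
#' @param genome Named character vector of contig sequences.
#' @param mirnas Named character vector of miRNA sequences.
#' @param cfg A [mirna_config()].
#' @return Data.frame of sites over all isoforms with a `gene_id` column.
#' @export
scan_gene_targets <- function(genes, genome, mirnas, cfg = mirna_config()) {
  rows <- list()
  for (g in genes) {
    for (tx in g$transcripts) {
      s <- scan_targets(transcript_sequence(tx, genome), mirnas, cfg,
                        transcript_id = tx$transcript_id)
      if (nrow(s)) { s$gene_id <- g$gene_id; rows[[length(rows) + 1L]] <- s }
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), mirna_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

site_genomic_range <- function(tx, start, end) {
  gpos <- to_genomic_coords(tx, start:(end - 1L))
  c(min(gpos), max(gpos) + 1L)
}

#' Classify AS-coupled miRNA regulation for one gene
#'
#' A (gene, miRNA) pair is AS-coupled when an equivalent target site (same
#' miRNA, overlapping genomic projection) is present in at least one
#' isoform and absent in at least one, and the site's genomic projection
#' intersects some AS event's alternative region. Genes with two or more
#' distinct miRNAs targeting one transcript are additionally flagged
#' multi-site.
#'
#' @param gene A `gene_model`.
#' @param events Events data.frame for the gene (from [classify_gene()]).
#' @param sites Sites data.frame for the gene's isoforms (from
#'   [scan_gene_targets()] or [scan_targets()]).
#' @return List with `by_mirna` data.frame (`mirna_id`, `n_isoforms_with`,
#'   `n_isoforms_without`, `in_alternative_region`, `as_coupled`),
#'   `as_coupled` (gene-level flag) and `multi_site`.
#' @export
coupled_as_mirna <- function(gene, events, sites) {
  iso_ids <- names(gene$transcripts)
  sites <- sites[sites$transcript_id %in% iso_ids, , drop = FALSE]
  mirnas <- unique(sites$mirna_id)
  rows <- list()
  for (mid in mirnas) {
    sub <- sites[sites$mirna_id == mid, , drop = FALSE]
    ranges <- lapply(seq_len(nrow(sub)), function(i)
      site_genomic_range(gene$transcripts[[sub$transcript_id[i]]],
                         sub$start[i], sub$end[i]))
    # cluster equivalent sites by genomic overlap
    cl <- seq_along(ranges)
    if (length(ranges) > 1L) {
      for (i in 2L:length(ranges)) for (j in 1L:(i - 1L)) {
        if (ranges[[i]][1L] < ranges[[j]][2L] &&
            ranges[[j]][1L] < ranges[[i]][2L]) cl[cl == cl[i]] <- cl[j]
      }
    }
    coupled <- FALSE; in_alt_any <- FALSE
    for (k in unique(cl)) {
      members <- which(cl == k)
      with_iso <- unique(sub$transcript_id[members])
      without <- setdiff(iso_ids, with_iso)
      span <- c(min(vapply(members, function(i) ranges[[i]][1L], integer(1))),
                max(vapply(members, function(i) ranges[[i]][2L], integer(1))))
      in_alt <- FALSE
      if (nrow(events)) {
        for (e in seq_len(nrow(events))) {
          reg <- parse_region(events$region[e])
          if (any(reg$starts < span[2L] & span[1L] < reg$ends)) in_alt <- TRUE
        }
      }
      in_alt_any <- in_alt_any || in_alt
      if (length(without) >= 1L && length(with_iso) >= 1L && in_alt)
        coupled <- TRUE
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$gene_id, mirna_id = mid,
      n_isoforms_with = length(unique(sub$transcript_id)),
      n_isoforms_without = length(setdiff(iso_ids,
                                          unique(sub$transcript_id))),
      in_alternative_region = in_alt_any, as_coupled = coupled,
      stringsAsFactors = FALSE)
  }
  by_mirna <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), mirna_id = character(),
               n_isoforms_with = integer(), n_isoforms_without = integer(),
               in_alternative_region = logical(), as_coupled = logical(),
               stringsAsFactors = FALSE)
  multi <- any(vapply(iso_ids, function(id)
    length(unique(sites$mirna_id[sites$transcript_id == id])) >= 2L,
    logical(1)))
  list(by_mirna = by_mirna, as_coupled = any(by_mirna$as_coupled),
       multi_site = multi)
}
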