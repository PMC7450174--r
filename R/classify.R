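# Pairwise alternative-splicing event classification.
#
# Events are local differences between two isoforms' splice structures,
# delimited by the nearest shared splice sites (or shared transcript
# termini). Typing is strand-aware: donor/acceptor and First/Last follow
# transcript orientation, never genomic left/right.

AS_EVENT_TYPES <- c("IR", "AltA", "AltD", "ES", "AltFirst", "AltLast",
                    "Complex")

exonic_at <- function(tx, pos) {
  vapply(as.integer(pos), function(p)
    any(tx$exon_starts <= p & p < tx$exon_ends), logical(1))
}

# three-valued membership at a single position: "E" exonic, "I" intronic
# (inside the transcript span but not exonic), "O" outside the span
membership_at <- function(tx, p) {
  if (p < tx$exon_starts[1L] || p >= tx$exon_ends[n_exons(tx)]) return("O")
  if (exonic_at(tx, p)) "E" else "I"
}

intron_starts <- function(tx) if (n_exons(tx) > 1L)
  tx$exon_ends[-n_exons(tx)] else integer()
intron_ends <- function(tx) if (n_exons(tx) > 1L)
  tx$exon_starts[-1L] else integer()

empty_events <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
             type = character(), isoform_a = character(),
             isoform_b = character(),
             region = character(), span_start = integer(),
             span_end = integer(), stringsAsFactors = FALSE)
}

region_string <- function(starts, ends) {
  paste(sprintf("%d-%d", starts, ends), collapse = ",")
}

#' Parse a region string back into interval starts/ends
#' @param region Region string such as `"100-200,300-350"`.
#' @return List with integer vectors `starts` and `ends`.
#' @export
parse_region <- function(region) {
  parts <- strsplit(strsplit(region, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  list(starts = vapply(parts, function(p) as.integer(p[1]), integer(1)),
       ends = vapply(parts, function(p) as.integer(p[2]), integer(1)))
}

#' Classify alternative-splicing events between two isoforms
#'
#' Differences between the exon structures of `a` and `b` are segmented into
#' maximal genomic runs where exactly one isoform is exonic; runs not
#' separated by a shared splice site are grouped into one event. Each event
#' is typed as intron retention (`IR`), alternative acceptor (`AltA`),
#' alternative donor (`AltD`), exon skipping (`ES`), alternative first or
#' last exon (`AltFirst`, `AltLast`), or `Complex` when no single template
#' fits. The alternative region is, by convention: for IR the retained
#' intron; for AltA/AltD the interval between the two alternate sites; for
#' ES the skipped exon; for AltFirst/AltLast the non-shared terminal exonic
#' spans.
#'
#' @param a,b `transcript_model` objects of the same gene.
#' @return Events data.frame with one row per event: `gene_id`, `chrom`,
#'   `strand`, `type`, `isoform_a`, `isoform_b`, `region` (comma-separated
#'   `start-end` intervals, 0-based half-open), `span_start`, `span_end`.
#' @export
classify_pair <- function(a, b) {
  if (a$gene_id != b$gene_id) stop("transcripts belong to different genes")
  if (a$chrom != b$chrom || a$strand != b$strand)
    stop("transcripts must share chrom and strand")
  strand <- a$strand

  pts <- sort(unique(c(a$exon_starts, a$exon_ends, b$exon_starts,
                       b$exon_ends)))
  if (length(pts) < 2L) return(empty_events())
  seg_start <- pts[-length(pts)]
  seg_end <- pts[-1L]
  inA <- exonic_at(a, seg_start)
  inB <- exonic_at(b, seg_start)
  dif <- inA != inB
  if (!any(dif)) return(empty_events())

  # maximal runs of differing segments
  r <- rle(dif)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values)
  run_tab <- lapply(runs, function(k) {
    sel <- idx_start[k]:idx_end[k]
    list(start = seg_start[sel[1L]], end = seg_end[sel[length(sel)]],
         ownerA = all(inA[sel]), ownerB = all(inB[sel]))
  })

  # shared splice sites separate events
  shared_sites <- sort(unique(c(
    intersect(intron_starts(a), intron_starts(b)),
    intersect(intron_ends(a), intron_ends(b)))))

  grp <- integer(length(run_tab)); grp[1L] <- 1L
  if (length(run_tab) > 1L) {
    for (i in 2L:length(run_tab)) {
      gap_lo <- run_tab[[i - 1L]]$end
      gap_hi <- run_tab[[i]]$start
      sep <- any(shared_sites >= gap_lo & shared_sites <= gap_hi)
      grp[i] <- if (sep) grp[i - 1L] + 1L else grp[i - 1L]
    }
  }

  a_start <- a$exon_starts[1L]; b_start <- b$exon_starts[1L]
  a_end <- a$exon_ends[n_exons(a)]; b_end <- b$exon_ends[n_exons(b)]

  out <- empty_events()
  for (g in unique(grp)) {
    rs <- run_tab[grp == g]
    span_start <- rs[[1L]]$start
    span_end <- rs[[length(rs)]]$end
    left_term <- (a_start != b_start) && span_start == min(a_start, b_start)
    right_term <- (a_end != b_end) && span_end == max(a_end, b_end)

    type <- "Complex"
    reg_starts <- vapply(rs, `[[`, integer(1), "start")
    reg_ends <- vapply(rs, `[[`, integer(1), "end")

    if (left_term && right_term) {
      type <- "Complex"
    } else if (left_term) {
      type <- if (strand == "+") "AltFirst" else "AltLast"
    } else if (right_term) {
      type <- if (strand == "+") "AltLast" else "AltFirst"
    } else if (length(rs) == 1L && (rs[[1L]]$ownerA || rs[[1L]]$ownerB)) {
      run <- rs[[1L]]
      lf <- c(membership_at(a, run$start - 1L), membership_at(b, run$start - 1L))
      rf <- c(membership_at(a, run$end), membership_at(b, run$end))
      if (all(lf == "E") && all(rf == "E")) {
        type <- "IR"
      } else if (all(lf == "I") && all(rf == "I")) {
        type <- "ES"
      } else if (all(lf == "I") && all(rf == "E")) {
        # introns share their genomic-left boundary, differ on the right
        type <- if (strand == "+") "AltA" else "AltD"
      } else if (all(lf == "E") && all(rf == "I")) {
        # introns share their genomic-right boundary, differ on the left
        type <- if (strand == "+") "AltD" else "AltA"
      }
    }

    out <- rbind(out, data.frame(
      gene_id = a$gene_id, chrom = a$chrom, strand = strand, type = type,
      isoform_a = a$transcript_id, isoform_b = b$transcript_id,
      region = region_string(reg_starts, reg_ends),
      span_start = span_start, span_end = span_end,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Classify all AS events of a gene
#'
#' Runs [classify_pair()] over every isoform pair and deduplicates the
#' events by `(type, region)`.
#'
#' @param gene A [gene_model()].
#' @return List with `events` (deduplicated events data.frame; the
#'   `isoform_a`/`isoform_b` columns keep the first pair that produced each
#'   event) and `is_as_gene` (`TRUE` iff any event was found or the gene has
#'   >= 2 isoforms).
#' @export
classify_gene <- function(gene) {
  txs <- gene$transcripts
  events <- empty_events()
  if (length(txs) >= 2L) {
    for (i in seq_len(length(txs) - 1L)) {
      for (j in (i + 1L):length(txs)) {
        events <- rbind(events, classify_pair(txs[[i]], txs[[j]]))
      }
    }
  }
  if (nrow(events)) {
    key <- paste(events$type, events$region)
    events <- events[!duplicated(key), , drop = FALSE]
    rownames(events) <- NULL
  }
  list(events = events,
       is_as_gene = nrow(events) > 0L || length(txs) >= 2L)
}

#' Event-type proportions over a set of events
#'
#' @param events Events data.frame (or a character vector of types).
#' @return Named numeric vector of fractions summing to 1.
#' @export
event_type_proportions <- function(events) {
  types <- if (is.data.frame(events)) events$type else events
  if (length(types) == 0L) stop("no events supplied")
  tab <- table(factor(types, levels = AS_EVENT_TYPES))
  p <- as.numeric(tab) / length(types)
  names(p) <- names(tab)
  p[p > 0 | names(p) %in% unique(types)]
}
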