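# Transcript-set filtering criteria applied to candidate assemblies:
# junction read support, tiered intron-retention coverage depth, and a
# minimum isoform abundance floor.

#' Filter configuration
#'
#' @param min_junction_reads Minimum reads supporting every junction of a
#'   retained transcript (default 3).
#' @param ir_depth_tiers Named numeric vector mapping covered-fraction tier
#'   floors (descending, in (0,1]) to minimum mean depths. The default
#'   requires mean depth 4 when the region is 100% covered, 5 when at least
#'   90% covered, 6 when at least 80% covered, and rejects below 80%.
#' @param min_isoform_abundance Minimum of the transcript's maximum
#'   abundance over all samples (default 5, FPKM-like units).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_junction_reads = 3L,
                          ir_depth_tiers = c("1.00" = 4, "0.90" = 5,
                                             "0.80" = 6),
                          min_isoform_abundance = 5) {
  fr <- as.numeric(names(ir_depth_tiers))
  if (any(is.na(fr)) || any(fr <= 0) || any(fr > 1) ||
      is.unsorted(rev(fr), strictly = TRUE))
    stop("ir_depth_tiers must be keyed by descending fractions in (0,1]")
  if (any(ir_depth_tiers <= 0)) stop("tier depths must be positive")
  structure(list(min_junction_reads = as.integer(min_junction_reads),
                 ir_depth_tiers = ir_depth_tiers,
                 min_isoform_abundance = min_isoform_abundance),
            class = "filter_config")
}

#' Junction read-support filter
#'
#' A transcript passes iff every one of its introns has a junction record
#' with read support at or above the threshold. Single-exon transcripts
#' pass vacuously; a missing junction record counts as zero support and is
#' reported.
#'
#' @param tx A `transcript_model`.
#' @param junctions Junction data.frame (`chrom`, `donor_end`,
#'   `acceptor_start`, `strand`, `read_support`), typically pooled over all
#'   libraries.
#' @param cfg A [filter_config()].
#' @return List with `pass` and a per-junction `report` data.frame
#'   (`donor_end`, `acceptor_start`, `read_support`, `found`, `ok`).
#' @export
junction_support_filter <- function(tx, junctions, cfg = filter_config()) {
  ins <- introns_of(tx)
  if (nrow(ins) == 0L) {
    return(list(pass = TRUE, report = data.frame(
      donor_end = integer(), acceptor_start = integer(),
      read_support = integer(), found = logical(), ok = logical())))
  }
  support <- integer(nrow(ins)); found <- logical(nrow(ins))
  for (i in seq_len(nrow(ins))) {
    hit <- which(junctions$chrom == ins$chrom[i] &
                 junctions$donor_end == ins$donor_end[i] &
                 junctions$acceptor_start == ins$acceptor_start[i] &
                 junctions$strand == ins$strand[i])
    if (length(hit)) {
      support[i] <- sum(junctions$read_support[hit])
      found[i] <- TRUE
    }
  }
  ok <- support >= cfg$min_junction_reads
  list(pass = all(ok),
       report = data.frame(donor_end = ins$donor_end,
                           acceptor_start = ins$acceptor_start,
                           read_support = support, found = found, ok = ok))
}

#' Tiered coverage-depth filter for intron-retention events
#'
#' Over the event's alternative region (the retained intron), the covered
#' fraction is the fraction of bases with depth >= 1 and the mean depth is
#' the arithmetic mean over the whole region. The region passes iff the
#' covered fraction reaches the lowest tier floor (0.80 by default) and the
#' mean depth reaches the tier minimum: with default tiers, depth >= 4 at
#' 100% coverage, >= 5 at [90%, 100%), >= 6 at [80%, 90%), fail below 80%.
#'
#' @param region_start,region_end Alternative region, 0-based half-open.
#' @param coverage Coverage track: list with `start` (0-based offset of the
#'   first depth value) and `depth` (numeric vector).
#' @param cfg A [filter_config()].
#' @return List with `pass`, `covered_fraction`, `mean_depth`,
#'   `required_depth` (NA when below the lowest tier).
#' @export
ir_coverage_filter <- function(region_start, region_end, coverage,
                               cfg = filter_config()) {
  region_start <- as.integer(region_start); region_end <- as.integer(region_end)
  if (region_end <= region_start) stop("empty alternative region")
  lo <- region_start - coverage$start
  hi <- region_end - coverage$start
  if (lo < 0L || hi > length(coverage$depth))
    stop("alternative region outside the coverage track")
  d <- coverage$depth[(lo + 1L):hi]
  covered_fraction <- mean(d >= 1)
  mean_depth <- mean(d)
  fr <- as.numeric(names(cfg$ir_depth_tiers))
  tier <- which(fr <= covered_fraction + 1e-12)
  if (length(tier) == 0L) {
    return(list(pass = FALSE, covered_fraction = covered_fraction,
                mean_depth = mean_depth, required_depth = NA_real_))
  }
  required <- unname(cfg$ir_depth_tiers[min(tier)])
  list(pass = mean_depth >= required, covered_fraction = covered_fraction,
       mean_depth = mean_depth, required_depth = required)
}

#' Abundance-floor filter
#'
#' A transcript is retained iff its maximum abundance over all samples
#' (conditions x replicates) is at least the configured floor.
#'
#' @param table Abundance data.frame (`transcript_id`, `condition`,
#'   `replicate`, `abundance`).
#' @param cfg A [filter_config()].
#' @return Character vector of retained transcript ids.
#' @export
abundance_floor_filter <- function(table, cfg = filter_config()) {
  mx <- tapply(table$abundance, table$transcript_id, max)
  names(mx)[mx >= cfg$min_isoform_abundance]
}

#' Apply all transcript filters to a gene set
#'
#' Computes the surviving transcript set as the intersection of the
#' junction-support filter, the IR coverage filter (applied to isoforms
#' carrying a retained intron), and the abundance floor. The composition is
#' order-independent.
#'
#' @param genes List of `gene_model`s.
#' @param junctions Pooled junction data.frame.
#' @param coverage Named list of per-contig coverage tracks.
#' @param table Abundance data.frame.
#' @param cfg A [filter_config()].
#' @return List with `keep` (character vector of retained transcript ids)
#'   and `report` (per-transcript data.frame of filter outcomes).
#' @export
filter_transcripts <- function(genes, junctions, coverage, table,
                               cfg = filter_config()) {
  ab_keep <- abundance_floor_filter(table, cfg)
  rows <- list()
  for (g in genes) {
    cls <- classify_gene(g)
    ir <- cls$events[cls$events$type == "IR", , drop = FALSE]
    for (tx in g$transcripts) {
      jf <- junction_support_filter(tx, junctions, cfg)
      ir_ok <- TRUE
      if (nrow(ir)) {
        for (k in seq_len(nrow(ir))) {
          reg <- parse_region(ir$region[k])
          # the IR filter constrains the isoform that retains the intron
          if (!all(exonic_at(tx, c(reg$starts, reg$ends - 1L)))) next
          cv <- coverage[[tx$chrom]]
          if (is.null(cv)) { ir_ok <- FALSE; next }
          res <- ir_coverage_filter(reg$starts, reg$ends, cv, cfg)
          ir_ok <- ir_ok && res$pass
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, transcript_id = tx$transcript_id,
        junction_pass = jf$pass, ir_pass = ir_ok,
        abundance_pass = tx$transcript_id %in% ab_keep,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  report$keep <- report$junction_pass & report$ir_pass & report$abundance_pass
  list(keep = report$transcript_id[report$keep], report = report)
}
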