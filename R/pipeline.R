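# End-to-end orchestration and summary reporting: isoform-count
# histograms, headline AS/NMD percentages, and a provenance-stamped run
# over all stages.

#' Published isoform-count table for the reference annotation and the
#' jasmonate-treatment assembly
#'
#' Gene counts by isoform number as printed for the TAIR10 reference
#' annotation and for the methyl-jasmonate RNA-seq transcript assembly.
#' Used to recompute the printed percentages exactly.
#'
#' @return Data.frame with `isoforms`, `tair10_genes`, `meja_genes`.
#' @export
isoform_count_table <- function() {
  data.frame(
    isoforms = 1:15,
    tair10_genes = c(21402L, 4251L, 1133L, 291L, 89L, 26L, 7L, 5L, 1L, 1L,
                     0L, 0L, 0L, 0L, 0L),
    meja_genes = c(9201L, 2998L, 881L, 345L, 115L, 65L, 21L, 11L, 6L, 0L,
                   1L, 2L, 0L, 0L, 1L))
}

#' Isoform-count histogram with percentages
#'
#' @param counts Named integer vector mapping isoform number to gene
#'   count.
#' @return Data.frame `isoforms`, `count`, `percent` (percent = 100 x
#'   count / total, reported to two decimals).
#' @export
isoform_histogram_percentages <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("zero total gene count")
  data.frame(isoforms = as.integer(names(counts)),
             count = as.integer(counts),
             percent = round(100 * as.numeric(counts) / total, 2))
}

#' Headline percentages of a summary report
#'
#' @param n_as_genes,n_genes AS genes and total genes.
#' @param n_nmd_genes,n_as_orf_genes NMD genes and AS genes with a usable
#'   ORF prediction.
#' @return Named list: `as_gene_percent` (two decimals),
#'   `nmd_gene_percent` (one decimal), following the printed precisions.
#' @export
headline_fractions <- function(n_as_genes, n_genes, n_nmd_genes = NA,
                               n_as_orf_genes = NA) {
  if (n_genes <= 0) stop("zero gene denominator")
  out <- list(as_gene_percent = round(100 * n_as_genes / n_genes, 2))
  if (!is.na(n_nmd_genes)) {
    if (is.na(n_as_orf_genes) || n_as_orf_genes <= 0)
      stop("zero AS-with-ORF denominator")
    out$nmd_gene_percent <- round(100 * n_nmd_genes / n_as_orf_genes, 1)
  }
  out
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}

provenance_header <- function(cfg, seed) {
  c(sprintf("# isoscope run"),
    sprintf("# seed: %d", seed),
    sprintf("# config_md5: %s", config_hash(cfg)))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a simulated (or loaded) study
#'
#' Stages run in order: transcript filtering, AS classification, ORF/NMD,
#' miRNA coupling, peptide validation, differential splicing, report.
#' Every output table carries a provenance header (seed, config hash);
#' identical configuration and seed give identical outputs.
#'
#' @param sim A study simulation (see [simulate_study()]).
#' @param out_dir Output directory for stage TSVs (created; `NULL` for no
#'   file output).
#' @param contrast Condition pair for the differential stages (defaults
#'   to the control/treated pair of the first genotype and tissue).
#' @param filter_cfg,mirna_cfg,min_len_aa,min_conf,min_overhang,n_perm
#'   Stage parameters.
#' @return List with all stage outputs and a `report` (see details), plus
#'   `seed`.
#' @details The report carries the isoform histogram, AS-gene count and
#'   percentage, NMD counts and percentage of AS genes with ORFs,
#'   event-type proportions, AS-coupled miRNA gene count and validated
#'   event count; percentages are always recomputed from the report's own
#'   counts.
#' @export
run_pipeline <- function(sim, out_dir = NULL, contrast = NULL,
                         filter_cfg = filter_config(),
                         mirna_cfg = mirna_config(), min_len_aa = 100L,
                         min_conf = 0.95, min_overhang = 1L,
                         n_perm = 1000L) {
  seed <- sim$design$seed
  cfg <- list(filter = unclass(filter_cfg), mirna = unclass(mirna_cfg),
              min_len_aa = min_len_aa, min_conf = min_conf,
              min_overhang = min_overhang, n_perm = n_perm, seed = seed)
  header <- provenance_header(cfg, seed)

  # stage 1: filtering
  filt <- filter_transcripts(sim$genes, sim$junctions, sim$coverage,
                             sim$abundance, filter_cfg)

  # stage 2: classification
  ev_rows <- list(); as_flags <- logical(length(sim$genes))
  names(as_flags) <- names(sim$genes)
  for (gid in names(sim$genes)) {
    cls <- classify_gene(sim$genes[[gid]])
    as_flags[gid] <- cls$is_as_gene
    if (nrow(cls$events)) ev_rows[[length(ev_rows) + 1L]] <- cls$events
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else empty_events()

  # stage 3: ORF + NMD
  orfs <- list(); nmd_rows <- list()
  for (gid in names(sim$genes)) {
    for (tx in sim$genes[[gid]]$transcripts) {
      orf <- find_orf(transcript_sequence(tx, sim$genome), min_len_aa)
      orfs[[tx$transcript_id]] <- orf
      if (orf$verdict == "ok") {
        v <- nmd_call(tx, orf)
        nmd_rows[[length(nmd_rows) + 1L]] <-
          data.frame(gene_id = gid, transcript_id = tx$transcript_id,
                     utr3_len = v$utr3_len,
                     stop_to_last_junction = v$stop_to_last_junction,
                     rule_long_utr3 = v$rule_long_utr3,
                     rule_junction_distance = v$rule_junction_distance,
                     nmd_candidate = v$nmd_candidate,
                     stringsAsFactors = FALSE)
      }
    }
  }
  nmd <- do.call(rbind, nmd_rows)

  # stage 4: miRNA coupling
  sites <- scan_gene_targets(sim$genes, sim$genome, sim$mirnas, mirna_cfg)
  coupled_rows <- list()
  for (gid in names(sim$genes)) {
    gsites <- sites[sites$gene_id == gid, , drop = FALSE]
    if (!nrow(gsites)) next
    cp <- coupled_as_mirna(sim$genes[[gid]],
                           events[events$gene_id == gid, , drop = FALSE],
                           gsites)
    coupled_rows[[length(coupled_rows) + 1L]] <-
      cbind(cp$by_mirna, multi_site = cp$multi_site)
  }
  coupled <- if (length(coupled_rows)) do.call(rbind, coupled_rows) else NULL

  # stage 5: peptide validation
  proteome <- data.frame(
    transcript_id = names(orfs),
    gene_id = vapply(names(orfs), function(id)
      sub("\\.[0-9]+$", "", id), ""),
    protein = vapply(orfs, function(o)
      if (o$verdict == "ok") o$protein else "", ""),
    stringsAsFactors = FALSE)
  proteome <- proteome[proteome$protein != "", , drop = FALSE]
  val <- validate_isoforms(sim$peptides, proteome, sim$genes, orfs, events,
                           min_conf = min_conf, min_overhang = min_overhang)

  # stage 6: differential splicing
  if (is.null(contrast)) {
    grid <- condition_labels(sim$design)
    base <- grid[grid$genotype == sim$design$genotypes[1L] &
                 grid$tissue == sim$design$tissues[1L], ]
    contrast <- base$condition[match(sim$design$treatments[1:2],
                                     base$treatment)]
  }
  multi_iso <- names(sim$genes)[vapply(sim$genes, function(g)
    length(g$transcripts) >= 2L, logical(1))]
  ds <- diff_splicing_test(
    sim$abundance[sim$abundance$gene_id %in% multi_iso, , drop = FALSE],
    contrast, n_perm = n_perm, seed = seed)
  ratios <- expression_ratio_matrix(sim$abundance, contrast)

  # report
  iso_counts <- table(vapply(sim$genes, function(g) length(g$transcripts),
                             integer(1)))
  histogram <- isoform_histogram_percentages(
    stats::setNames(as.integer(iso_counts), names(iso_counts)))
  n_genes <- length(sim$genes)
  n_as <- sum(as_flags)
  orf_ok <- vapply(orfs, function(o) o$verdict == "ok", logical(1))
  as_orf_genes <- unique(proteome$gene_id[
    proteome$gene_id %in% names(as_flags)[as_flags]])
  nmd_genes <- unique(nmd$gene_id[nmd$nmd_candidate])
  nmd_genes <- intersect(nmd_genes, as_orf_genes)
  report <- list(
    histogram = histogram, n_genes = n_genes, n_as_genes = n_as,
    as_gene_percent = headline_fractions(n_as, n_genes)$as_gene_percent,
    n_nmd_transcripts = if (is.null(nmd)) 0L else sum(nmd$nmd_candidate),
    n_nmd_genes = length(nmd_genes),
    n_as_orf_genes = length(as_orf_genes),
    nmd_gene_percent = if (length(as_orf_genes))
      headline_fractions(0, 1, length(nmd_genes),
                         length(as_orf_genes))$nmd_gene_percent else NA,
    event_type_proportions = if (nrow(events))
      event_type_proportions(events) else NULL,
    n_as_coupled_mirna_genes = if (is.null(coupled)) 0L else
      length(unique(coupled$gene_id[coupled$as_coupled])),
    n_validated_events = length(unique(paste(val$validated$gene_id,
                                             val$validated$region))),
    n_transcripts_kept = length(filt$keep))

  out <- list(seed = seed, filter = filt, events = events, nmd = nmd,
              orfs = orfs, sites = sites, coupled = coupled,
              validation = val, diff_splicing = ds, ratios = ratios,
              report = report, contrast = contrast)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_with_header(filt$report, file.path(out_dir, "filter.tsv"),
                          header)
    write_tsv_with_header(events, file.path(out_dir, "events.tsv"), header)
    write_tsv_with_header(nmd, file.path(out_dir, "nmd.tsv"), header)
    write_tsv_with_header(sites, file.path(out_dir, "mirna_sites.tsv"),
                          header)
    if (!is.null(coupled))
      write_tsv_with_header(coupled, file.path(out_dir, "mirna_coupled.tsv"),
                            header)
    write_tsv_with_header(val$validated,
                          file.path(out_dir, "validated_events.tsv"), header)
    write_tsv_with_header(ds, file.path(out_dir, "diff_splicing.tsv"),
                          header)
    write_tsv_with_header(ratios, file.path(out_dir, "expression_ratios.tsv"),
                          header)
    write_tsv_with_header(histogram, file.path(out_dir, "isoform_histogram.tsv"),
                          header)
  }
  out
}
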