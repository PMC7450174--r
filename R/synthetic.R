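# Synthetic annotated loci with planted ground truth: AS events, ORFs and
# NMD status, miRNA target sites, junction-spanning peptides, and
# replicate abundance/junction/coverage data under a multi-genotype,
# multi-tissue, +-treatment design.
#
# A locus is laid out in "logical" coordinates (left = transcript 5'); a
# minus-strand locus is produced by reflecting the finished layout and
# reverse-complementing the contig, so planting code is strand-free while
# every downstream consumer sees genuine minus-strand geometry.
#
# Each requested event type occupies its own slot, and any two slots are
# separated by at least one splice site shared by every isoform, so the
# pairwise classifier recovers exactly the planted (type, region) set.
# Isoforms form a chain: isoform k+1 carries the first k planted events.

AS_PLANT_TYPES <- c("AltFirst", "ES", "AltD", "IR", "AltA", "AltLast")

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0)), c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))
# codons free of K/R/P/stop, used where the tryptic frame must be controlled
SAFE_CODONS <- c("GCT", "GTT", "TCT", "GAT", "GAA", "CTT", "ACT")

translate_dna <- function(s) {
  n <- nchar(s) %/% 3L
  cod <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"                  # codons containing N
  paste(aa, collapse = "")
}

random_dna <- function(rng, len) {
  paste(sample_vec(rng, c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# 5'UTR piece: no ATG anywhere, starts with C, ends with CC, so arbitrary
# concatenations of pieces can never form a start codon across a junction
utr5_piece <- function(rng, len) {
  s <- random_dna(rng, len)
  repeat {
    m <- regexpr("ATG", s, fixed = TRUE)
    if (m == -1L) break
    substr(s, m + 2L, m + 2L) <- "C"
  }
  substr(s, 1L, 1L) <- "C"
  if (len >= 3L) substr(s, len - 1L, len) <- "CC"
  s
}

#' Specification of one synthetic locus
#'
#' @param event_types Character vector drawn from
#'   `AltFirst, ES, AltD, IR, AltA, AltLast` (at most one of each; empty
#'   for a single-isoform locus).
#' @param seed Integer seed; generation is a pure function of it.
#' @param cds_exon_len,utr_exon_len,intron_len,ir_intron_len Integer
#'   length ranges (`c(lo, hi)`) for coding exons, untranslated exons,
#'   ordinary introns and retained introns. Retained introns are kept
#'   short enough that no spurious ORF can outgrow the planted one, and
#'   long enough that a premature stop inside them leaves a 3'UTR over
#'   350 nt.
#' @return A list of class `locus_spec`.
#' @export
locus_spec <- function(event_types = "IR", seed = 1L,
                       cds_exon_len = c(300L, 360L),
                       utr_exon_len = c(40L, 90L),
                       intron_len = c(80L, 150L),
                       ir_intron_len = c(160L, 180L)) {
  event_types <- as.character(event_types)
  if (anyDuplicated(event_types))
    stop("locus spec error: duplicated event types")
  bad <- setdiff(event_types, AS_PLANT_TYPES)
  if (length(bad))
    stop("locus spec error: unknown event type(s) ", paste(bad, collapse = ", "))
  if (intron_len[1] < 20L || ir_intron_len[1] < 20L)
    stop("locus spec error: intron range below the minimum intron size")
  structure(list(event_types = event_types,
                 n_isoforms = length(event_types) + 1L,
                 seed = as.integer(seed), cds_exon_len = cds_exon_len,
                 utr_exon_len = utr_exon_len, intron_len = intron_len,
                 ir_intron_len = ir_intron_len),
            class = "locus_spec")
}

#' Generate one synthetic locus with a planted-event ledger
#'
#' @param spec A [locus_spec()].
#' @param gene_id Gene identifier (also names the contig `chr_<gene_id>`).
#' @param strand `"+"` or `"-"`.
#' @return List with `gene` (a `gene_model`; isoform 1 is the primary),
#'   `genome` (named contig sequence), `events` (planted ledger in the
#'   classifier's output format), `truth` (per-isoform data.frame:
#'   `transcript_id`, `cds_start_tx`, `stop_tx`, `utr3_len`,
#'   `stop_to_last_junction`, `nmd`, `protein`), and `meta` (planting
#'   coordinates used by the miRNA/peptide generators).
#' @export
make_locus <- function(spec, gene_id = "G0001", strand = "+") {
  rng <- make_rng(spec$seed)
  ev <- spec$event_types
  has <- function(t) t %in% ev

  margin <- 50L
  cur <- margin
  prim <- list()        # primary exons, logical coords
  take <- function(len) {
    s <- cur; cur <<- cur + as.integer(len)
    prim[[length(prim) + 1L]] <<- c(s, cur)
    c(s, cur)
  }
  reserve <- function(len) { s <- cur; cur <<- cur + as.integer(len); c(s, cur) }
  gap <- function(len) cur <<- cur + as.integer(len)
  rexon <- function(range) rint(rng, range[1], range[2])

  slot <- list()
  # --- 5'UTR slots -----------------------------------------------------
  if (has("AltFirst")) {
    slot$F <- take(rexon(spec$utr_exon_len + 20L))
    gap(30L)
    slot$Fp <- reserve(rexon(spec$utr_exon_len + 20L))
    gap(30L)
    take(rexon(spec$utr_exon_len))                 # buffer B1
  } else {
    take(rexon(spec$utr_exon_len + 20L))           # first exon
  }
  if (has("ES")) {
    gap(rint(rng, 60L, 100L))
    slot$Es <- take(rexon(c(45L, 70L)))
    gap(rint(rng, 60L, 100L))
    take(rexon(spec$utr_exon_len))                 # buffer B2
  }
  if (has("AltD")) {
    slot$bd_end <- prim[[length(prim)]][2]         # donor of the next intron
    slot$s_d <- rint(rng, 8L, 15L)
  }
  # --- CDS exons -------------------------------------------------------
  gap(rint(rng, 90L, 140L))
  C1 <- take(rexon(spec$cds_exon_len))
  gap(rint(rng, spec$intron_len[1], spec$intron_len[2]))
  C2 <- take(rexon(spec$cds_exon_len))
  gap(rint(rng, spec$intron_len[1], spec$intron_len[2]))
  C3 <- take(rexon(spec$cds_exon_len))
  g_ir <- if (has("IR")) rint(rng, spec$ir_intron_len[1], spec$ir_intron_len[2])
          else rint(rng, spec$intron_len[1], spec$intron_len[2])
  gap(g_ir)
  C4 <- take(rexon(spec$cds_exon_len))
  if (has("IR")) slot$ir <- c(C3[2], C4[1])
  # --- 3'UTR slots -----------------------------------------------------
  utr3_slot <- has("AltA") || has("AltLast")
  trail <- if (utr3_slot) 20L else rint(rng, 130L, 180L)
  if (has("AltA") && has("AltLast")) {
    gap(rint(rng, 80L, 130L))
    X1 <- take(18L); slot$x1_start <- X1[1]; slot$s_a <- rint(rng, 4L, 7L)
    gap(rint(rng, 30L, 60L)); take(14L)            # buffer X2
    gap(rint(rng, 30L, 60L)); slot$En <- take(60L)
    gap(30L); slot$Enp <- reserve(70L)
  } else if (has("AltA")) {
    gap(rint(rng, 80L, 130L))
    X1 <- take(60L); slot$x1_start <- X1[1]; slot$s_a <- rint(rng, 8L, 20L)
  } else if (has("AltLast")) {
    gap(rint(rng, 80L, 130L))
    slot$En <- take(rexon(c(60L, 80L)))
    gap(30L); slot$Enp <- reserve(rexon(c(60L, 80L)))
  }
  contig_len <- cur + margin

  prim_mat <- do.call(rbind, prim)
  utr5_exons <- prim_mat[prim_mat[, 1] < C1[1], , drop = FALSE]
  utr3_exons <- prim_mat[prim_mat[, 1] > C4[1], , drop = FALSE]

  # --- CDS arithmetic --------------------------------------------------
  utr5_tail <- rint(rng, 30L, 45L)
  c4cds <- (C4[2] - C4[1]) - trail
  total0 <- (C1[2] - C1[1] - utr5_tail) + (C2[2] - C2[1]) +
    (C3[2] - C3[1]) + c4cds
  utr5_tail <- utr5_tail + (total0 %% 3L)
  total_cds <- (C1[2] - C1[1] - utr5_tail) + (C2[2] - C2[1]) +
    (C3[2] - C3[1]) + c4cds                        # includes the stop codon
  n_cod <- total_cds %/% 3L
  cds_before_ir <- (C1[2] - C1[1] - utr5_tail) + (C2[2] - C2[1]) +
    (C3[2] - C3[1])                                # CDS nt 5' of the IR intron

  codons <- c("ATG", sample_vec(rng, SENSE_CODONS, n_cod - 2L,
                                replace = TRUE), "TAA")
  nres_before <- cds_before_ir %/% 3L
  phase <- cds_before_ir %% 3L
  if (has("IR")) {
    # engineer a tryptic peptide spanning the exon/retained-intron boundary
    codons[nres_before - 4L] <- "AAA"
    codons[(nres_before - 3L):nres_before] <-
      sample_vec(rng, SAFE_CODONS, 4L, replace = TRUE)
    if (phase > 0L) codons[nres_before + 1L] <- "GCT"
  }
  cds_seq <- paste(codons, collapse = "")

  # --- mRNA assembly ---------------------------------------------------
  utr5_lens <- c(utr5_exons[, 2] - utr5_exons[, 1], utr5_tail)
  utr5_seq <- paste(vapply(utr5_lens, function(l) utr5_piece(rng, l), ""),
                    collapse = "")
  utr3_len_total <- trail + sum(utr3_exons[, 2] - utr3_exons[, 1])
  utr3_seq <- random_dna(rng, utr3_len_total)
  mrna <- paste0(utr5_seq, cds_seq, utr3_seq)
  stopifnot(nchar(mrna) == sum(prim_mat[, 2] - prim_mat[, 1]))

  gseq <- random_dna(rng, contig_len)
  pos <- 1L
  for (i in seq_len(nrow(prim_mat))) {
    len <- prim_mat[i, 2] - prim_mat[i, 1]
    substr(gseq, prim_mat[i, 1] + 1L, prim_mat[i, 2]) <-
      substr(mrna, pos, pos + len - 1L)
    pos <- pos + len
  }
  if (has("AltFirst")) {
    l <- slot$Fp[2] - slot$Fp[1]
    substr(gseq, slot$Fp[1] + 1L, slot$Fp[2]) <- utr5_piece(rng, l)
  }
  if (has("AltD")) {
    substr(gseq, slot$bd_end + 1L, slot$bd_end + slot$s_d) <-
      utr5_piece(rng, slot$s_d)
  }
  ir_pad <- (3L - phase) %% 3L
  if (has("IR")) {
    # retained-intron prefix: in-frame safe codons, a K, then a stop (PTC)
    prefix <- if (phase == 1L) "CT" else if (phase == 2L) "T" else ""
    body <- paste0(prefix,
                   paste(sample_vec(rng, SAFE_CODONS, 4L, replace = TRUE),
                         collapse = ""), "AAA", "TAA")
    substr(gseq, slot$ir[1] + 1L, slot$ir[1] + nchar(body)) <- body
  }

  # --- isoform chain ---------------------------------------------------
  apply_event <- function(ex, type) {
    drop_at <- function(ex, s) ex[vapply(ex, function(e) e[1] != s,
                                         logical(1))]
    ex <- switch(type,
      AltFirst = c(drop_at(ex, slot$F[1]), list(slot$Fp)),
      ES = drop_at(ex, slot$Es[1]),
      AltD = lapply(ex, function(e)
        if (e[2] == slot$bd_end) c(e[1], e[2] + slot$s_d) else e),
      IR = {
        keep <- ex[vapply(ex, function(e)
          e[2] != slot$ir[1] && e[1] != slot$ir[2], logical(1))]
        left <- ex[vapply(ex, function(e) e[2] == slot$ir[1], logical(1))]
        right <- ex[vapply(ex, function(e) e[1] == slot$ir[2], logical(1))]
        c(keep, list(c(left[[1]][1], right[[1]][2])))
      },
      AltA = lapply(ex, function(e)
        if (e[1] == slot$x1_start) c(e[1] + slot$s_a, e[2]) else e),
      AltLast = c(drop_at(ex, slot$En[1]), list(slot$Enp)))
    ex[order(vapply(ex, `[`, integer(1), 1))]
  }

  present <- AS_PLANT_TYPES[AS_PLANT_TYPES %in% ev]   # 5'->3' slot order
  iso_exons <- list(lapply(seq_len(nrow(prim_mat)),
                           function(i) c(prim_mat[i, 1], prim_mat[i, 2])))
  for (t in present)
    iso_exons[[length(iso_exons) + 1L]] <-
      apply_event(iso_exons[[length(iso_exons)]], t)

  # --- strand handling -------------------------------------------------
  chrom <- paste0("chr_", gene_id)
  refl <- function(iv) c(contig_len - iv[2], contig_len - iv[1])
  refl_b <- function(b) contig_len - b
  if (strand == "-") gseq <- revcomp(gseq)
  to_gen <- function(iv) if (strand == "-") refl(iv) else iv
  to_gen_b <- function(b) if (strand == "-") refl_b(b) else b

  iso_ids <- paste0(gene_id, ".", seq_along(iso_exons))
  txs <- lapply(seq_along(iso_exons), function(k) {
    ivs <- lapply(iso_exons[[k]], to_gen)
    m <- do.call(rbind, ivs)
    transcript_model(iso_ids[k], gene_id, chrom, strand, m[, 1], m[, 2])
  })
  gene <- gene_model(gene_id, txs)
  genome <- stats::setNames(gseq, chrom)

  # --- planted-event ledger --------------------------------------------
  ev_rows <- lapply(seq_along(present), function(k) {
    t <- present[k]
    regions <- switch(t,
      AltFirst = list(slot$F, slot$Fp),
      ES = list(slot$Es),
      AltD = list(c(slot$bd_end, slot$bd_end + slot$s_d)),
      IR = list(slot$ir),
      AltA = list(c(slot$x1_start, slot$x1_start + slot$s_a)),
      AltLast = list(slot$En, slot$Enp))
    regions <- lapply(regions, to_gen)
    regions <- regions[order(vapply(regions, `[`, integer(1), 1))]
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand, type = t,
               isoform_a = iso_ids[1], isoform_b = iso_ids[k + 1L],
               region = region_string(
                 vapply(regions, `[`, integer(1), 1),
                 vapply(regions, `[`, integer(1), 2)),
               stringsAsFactors = FALSE)
  })
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    empty_events()[, c("gene_id", "chrom", "strand", "type", "isoform_a",
                       "isoform_b", "region")]

  cds_boundary <- to_gen_b(C1[1] + utr5_tail)
  meta <- list(gene_id = gene_id, chrom = chrom, strand = strand,
               contig_len = contig_len, cds_boundary = cds_boundary,
               nres_before = if (has("IR")) nres_before else NA_integer_,
               ir_boundary = if (has("IR")) to_gen_b(slot$ir[1]) else NA,
               ir_region = if (has("IR")) to_gen(slot$ir) else NULL,
               ir_pad = ir_pad,
               ir_isoform = if (has("IR"))
                 iso_ids[which(present == "IR") + 1L] else NA_character_,
               # logical window inside the retained intron, past the PTC,
               # where a miRNA site may be planted
               ir_site_window = if (has("IR"))
                 c(slot$ir[1] + ir_pad + 25L, slot$ir[2] - 26L) else NULL,
               # logical window in the shared terminal 3'UTR (no 3' slots)
               shared_site_window = if (!utr3_slot)
                 c(C4[1] + c4cds + 20L, C4[2] - 31L) else NULL,
               c1_cds_start_logical = C1[1] + utr5_tail,
               cds_codons = codons, strand_reflect = strand == "-",
               has_ir = has("IR"))

  truth <- locus_truth(gene, genome, cds_boundary)
  list(gene = gene, genome = genome, events = events, truth = truth,
       meta = meta)
}

# per-isoform ground truth: single-frame scan from the known CDS start
locus_truth <- function(gene, genome, cds_boundary,
                        utr3_threshold = 350, junction_threshold = 55) {
  rows <- lapply(gene$transcripts, function(tx) {
    s <- transcript_sequence(tx, genome)
    L <- nchar(s)
    cds_start <- transcript_bases_before(tx, cds_boundary)
    ncod <- (L - cds_start) %/% 3L
    cod <- substring(s, cds_start + 3L * (seq_len(ncod) - 1L) + 1L,
                     cds_start + 3L * seq_len(ncod))
    stop_i <- which(cod %in% c("TAA", "TAG", "TGA"))[1L]
    if (is.na(stop_i)) stop("no stop codon downstream of the planted start")
    stop_tx <- cds_start + 3L * (stop_i - 1L)
    protein <- translate_dna(substr(s, cds_start + 1L, stop_tx))
    utr3 <- L - stop_tx - 3L
    k <- n_exons(tx)
    lens <- tx$exon_ends - tx$exon_starts
    if (tx$strand == "-") lens <- rev(lens)
    dist <- if (k < 2L) -Inf else sum(lens[-k]) - stop_tx
    data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
               cds_start_tx = cds_start, stop_tx = stop_tx,
               utr3_len = utr3, stop_to_last_junction = dist,
               nmd = utr3 > utr3_threshold ||
                 (is.finite(dist) && dist > junction_threshold),
               protein = protein, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Study design for the synthetic experiment
#'
#' Defaults emulate a three-genotype (wild type plus two mutants), two
#' tissue, control-versus-treatment design with three replicates.
#'
#' @param genotypes,tissues,treatments Factor levels; the first treatment
#'   is the control level.
#' @param replicates Replicates per condition (>= 2).
#' @param differential_fraction Fraction of multi-isoform loci given a
#'   planted isoform-proportion shift between treatment levels.
#' @param delta Planted proportion shift, in (0, 1].
#' @param depth Mean read depth scaling junction support and coverage.
#' @param sigma Log-normal replicate noise SD on abundances.
#' @param seed Integer seed.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(genotypes = c("WT", "jaz2", "jaz7"),
                        tissues = c("shoot", "root"),
                        treatments = c("mock", "MeJA"),
                        replicates = 3L, differential_fraction = 0.2,
                        delta = 0.3, depth = 20, sigma = 0.25, seed = 1L) {
  if (replicates < 2L) stop("need >= 2 replicates per condition")
  if (delta <= 0 || delta > 1) stop("delta must be in (0, 1]")
  structure(list(genotypes = genotypes, tissues = tissues,
                 treatments = treatments, replicates = as.integer(replicates),
                 differential_fraction = differential_fraction, delta = delta,
                 depth = depth, sigma = sigma, seed = as.integer(seed)),
            class = "design_spec")
}

condition_labels <- function(design) {
  grid <- expand.grid(treatment = design$treatments, tissue = design$tissues,
                      genotype = design$genotypes, stringsAsFactors = FALSE)
  grid$condition <- paste(grid$genotype, grid$tissue, grid$treatment,
                          sep = ".")
  grid
}

#' Simulate abundances, junction supports and coverage for gene models
#'
#' Replicate abundances are log-normal around condition means; pooled
#' junction read supports are Poisson with mean proportional to the
#' summed proportion of supporting isoforms times the design depth;
#' per-base coverage is Poisson around the isoform-mixture depth.
#' Differential loci receive a proportion shift of `delta` from the
#' primary to the second isoform under non-control treatments.
#'
#' @param genes Named list of `gene_model`s.
#' @param design A [design_spec()].
#' @param contig_lengths Named integer vector (contig -> length) for
#'   coverage simulation; defaults to the span of each gene's contig.
#' @return List with `abundance` (long data.frame), `junctions` (pooled
#'   support data.frame), `coverage` (named list of tracks), `truth`
#'   (per-gene `differential` flag, planted proportions).
#' @export
simulate_counts <- function(genes, design, contig_lengths = NULL) {
  rng <- make_rng(design$seed + 77003L)
  grid <- condition_labels(design)
  ab_rows <- list(); jn_rows <- list(); truth_rows <- list()
  coverage <- list()
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(genes, function(g)
      max(vapply(g$transcripts, function(tx) max(tx$exon_ends), integer(1))) +
        50L, integer(1))
    names(contig_lengths) <- vapply(genes, `[[`, "", "chrom")
  }
  for (g in genes) {
    txs <- g$transcripts
    K <- length(txs)
    mu <- exp(rnorm_n(rng, 1L, log(50), 0.7))
    diff_locus <- K >= 2L && rbern(rng, 1L, design$differential_fraction)
    p1 <- runif_n(rng, 1L, max(0.5, design$delta + 0.15), 0.8)
    rest <- if (K > 1L) {
      w <- rgamma_n(rng, K - 1L, 2)
      (1 - p1) * w / sum(w)
    } else numeric()
    pi_ctrl <- if (K == 1L) 1 else c(p1, rest)
    pi_trt <- pi_ctrl
    if (diff_locus) {
      pi_trt[1L] <- pi_ctrl[1L] - design$delta
      pi_trt[2L] <- pi_ctrl[2L] + design$delta
    }
    pi_by_cond <- lapply(seq_len(nrow(grid)), function(i)
      if (grid$treatment[i] == design$treatments[1L]) pi_ctrl else pi_trt)

    for (i in seq_len(nrow(grid))) {
      for (r in seq_len(design$replicates)) {
        noise <- exp(rnorm_n(rng, K, 0, design$sigma))
        ab <- mu * pi_by_cond[[i]] * noise
        ab_rows[[length(ab_rows) + 1L]] <- data.frame(
          transcript_id = names(txs), gene_id = g$gene_id,
          condition = grid$condition[i], replicate = r, abundance = ab,
          stringsAsFactors = FALSE)
      }
    }

    # pooled junction supports: mean isoform share over conditions
    w_iso <- Reduce(`+`, pi_by_cond) / length(pi_by_cond)
    jn_key <- list()
    for (k in seq_len(K)) {
      ins <- introns_of(txs[[k]])
      for (j in seq_len(nrow(ins))) {
        key <- paste(ins$donor_end[j], ins$acceptor_start[j])
        if (is.null(jn_key[[key]])) {
          jn_key[[key]] <- list(chrom = ins$chrom[j],
                                donor_end = ins$donor_end[j],
                                acceptor_start = ins$acceptor_start[j],
                                strand = ins$strand[j], share = 0)
        }
        jn_key[[key]]$share <- jn_key[[key]]$share + w_iso[k]
      }
    }
    for (key in names(jn_key)) {
      x <- jn_key[[key]]
      jn_rows[[length(jn_rows) + 1L]] <- data.frame(
        chrom = x$chrom, donor_end = x$donor_end,
        acceptor_start = x$acceptor_start, strand = x$strand,
        read_support = rpois_n(rng, 1L, design$depth * x$share),
        stringsAsFactors = FALSE)
    }

    # coverage: isoform-mixture depth with Poisson noise
    L <- contig_lengths[[g$chrom]]
    lam <- numeric(L)
    for (k in seq_len(K)) {
      tx <- txs[[k]]
      for (e in seq_len(n_exons(tx)))
        lam[(tx$exon_starts[e] + 1L):tx$exon_ends[e]] <-
          lam[(tx$exon_starts[e] + 1L):tx$exon_ends[e]] +
          design$depth * w_iso[k]
    }
    coverage[[g$chrom]] <- list(start = 0L,
                                depth = rpois_n(rng, L, lam))
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, differential = diff_locus,
      delta = if (diff_locus) design$delta else 0,
      p1_control = pi_ctrl[1L], stringsAsFactors = FALSE)
  }
  list(abundance = do.call(rbind, ab_rows),
       junctions = do.call(rbind, jn_rows),
       coverage = coverage,
       truth = do.call(rbind, truth_rows))
}

#' Plant miRNA target sites into a simulated genome
#'
#' Each planted site is the exact reverse complement of a random 21-nt
#' miRNA written into one location: either inside a retained intron
#' (present only in intron-retaining isoforms — an alternative-region
#' site) or in the shared terminal 3'UTR (present in every isoform).
#' Unplanted miRNAs are decoys with no target anywhere.
#'
#' @param sim A study simulation (from [simulate_study()] or a compatible
#'   list with `genome` and `metas`).
#' @param n_mirnas Number of miRNAs to emit.
#' @param seed Integer seed.
#' @param frac_alternative Fraction of planted sites placed inside
#'   alternative regions.
#' @return List with `mirnas` (named RNA strings), `ledger` (data.frame:
#'   `mirna_id`, `gene_id`, `transcript_id` of the retaining isoform or
#'   NA for shared sites, `site_start`, `site_end` genomic,
#'   `in_alternative_region`), and the modified `genome`.
#' @export
plant_mirna_targets <- function(sim, n_mirnas = 12L, seed = 1L,
                                frac_alternative = 0.6) {
  rng <- make_rng(seed + 4099L)
  genome <- sim$genome
  mirnas <- stats::setNames(
    vapply(seq_len(n_mirnas), function(i)
      paste(sample_vec(rng, c("A", "C", "G", "U"), 21L, replace = TRUE),
            collapse = ""), ""),
    sprintf("mir%03d", seq_len(n_mirnas)))
  alt_loci <- Filter(function(m) !is.null(m$ir_site_window), sim$metas)
  shared_loci <- Filter(function(m) !is.null(m$shared_site_window), sim$metas)
  n_alt <- min(length(alt_loci), round(n_mirnas * frac_alternative))
  n_shared <- min(length(shared_loci), n_mirnas - n_alt)
  picks <- list()
  if (n_alt > 0L)
    for (i in seq_len(n_alt))
      picks[[length(picks) + 1L]] <- list(meta = alt_loci[[i]], alt = TRUE)
  if (n_shared > 0L)
    for (i in seq_len(n_shared))
      picks[[length(picks) + 1L]] <- list(meta = shared_loci[[i]], alt = FALSE)

  rows <- list()
  for (i in seq_along(picks)) {
    meta <- picks[[i]]$meta
    win <- if (picks[[i]]$alt) meta$ir_site_window else meta$shared_site_window
    if (win[2] - win[1] < 21L) next
    s_log <- rint(rng, win[1], win[2] - 21L)
    site_log <- c(s_log, s_log + 21L)
    g <- if (meta$strand == "-")
      c(meta$contig_len - site_log[2], meta$contig_len - site_log[1])
    else site_log
    mid <- names(mirnas)[i]
    site_seq <- revcomp(chartr("U", "T", mirnas[[mid]]))   # mRNA content
    written <- if (meta$strand == "-") revcomp(site_seq) else site_seq
    contig <- genome[[meta$chrom]]
    substr(contig, g[1] + 1L, g[2]) <- written
    genome[[meta$chrom]] <- contig
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = mid, gene_id = meta$gene_id,
      transcript_id = if (picks[[i]]$alt) meta$ir_isoform else NA_character_,
      site_start = g[1], site_end = g[2],
      in_alternative_region = picks[[i]]$alt, stringsAsFactors = FALSE)
  }
  list(mirnas = mirnas,
       ledger = if (length(rows)) do.call(rbind, rows) else
         data.frame(mirna_id = character(), gene_id = character(),
                    transcript_id = character(), site_start = integer(),
                    site_end = integer(), in_alternative_region = logical(),
                    stringsAsFactors = FALSE),
       genome = genome)
}

#' Generate a peptide table with planted junction evidence and decoys
#'
#' Proteins are digested with trypsin rules (cleave after K/R, not before
#' P). For each intron-retention locus the engineered tryptic peptide
#' spanning the exon/retained-intron junction of the retaining isoform is
#' emitted; non-junction decoys are sampled from constitutive CDS regions;
#' ambiguous peptides planted into two genes are included. A configurable
#' fraction of confidences falls below 0.95.
#'
#' @param sim Study simulation with `proteome`, `truth`, `metas`, `genes`.
#' @param seed Integer seed.
#' @param frac_low Fraction of peptides drawn with confidence below 0.95.
#' @param decoys_per_locus Non-junction decoys sampled per locus.
#' @return List with `records` (`sequence`, `confidence`) and `ledger`
#'   (adds `class` in junction/decoy/ambiguous, `gene_id`,
#'   `transcript_id`, `boundary`).
#' @export
make_peptides <- function(sim, seed = 1L, frac_low = 0.2,
                          decoys_per_locus = 1L) {
  rng <- make_rng(seed + 90001L)
  rows <- list()
  add <- function(sequence, class, gene_id, transcript_id, boundary = NA) {
    conf <- if (rbern(rng, 1L, frac_low)) runif_n(rng, 1L, 0.5, 0.9489)
            else runif_n(rng, 1L, 0.951, 0.9999)
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = sequence, confidence = conf, class = class,
      gene_id = gene_id, transcript_id = transcript_id,
      boundary = boundary, stringsAsFactors = FALSE)
  }
  ambiguous_seqs <- unlist(lapply(sim$ambiguous, `[[`, "sequence"))
  for (meta in sim$metas) {
    gid <- meta$gene_id
    prot_prim <- sim$proteome$protein[
      sim$proteome$transcript_id == paste0(gid, ".1")]
    if (meta$has_ir) {
      tid <- meta$ir_isoform
      tx <- sim$genes[[gid]]$transcripts[[tid]]
      prot <- sim$proteome$protein[sim$proteome$transcript_id == tid]
      tr <- sim$truth[sim$truth$transcript_id == tid, ]
      t_nt <- transcript_bases_before(tx, meta$ir_boundary)
      peps <- tryptic_digest(prot)
      ends <- cumsum(nchar(peps)); starts <- ends - nchar(peps) + 1L
      nt_s <- tr$cds_start_tx + 3L * (starts - 1L)
      nt_e <- tr$cds_start_tx + 3L * ends
      span <- (t_nt - nt_s) %/% 3L >= 4L & (nt_e - t_nt) %/% 3L >= 4L
      if (any(span))
        add(peps[which(span)[1L]], "junction", gid, tid, meta$ir_boundary)
    }
    # decoys: constitutive CDS peptides far from any planted boundary
    peps <- tryptic_digest(prot_prim)
    ends <- cumsum(nchar(peps)); starts <- ends - nchar(peps) + 1L
    lim <- if (meta$has_ir) meta$nres_before - 12L else nchar(prot_prim) - 12L
    ok <- which(nchar(peps) >= 7L & nchar(peps) <= 15L & starts >= 10L &
                  ends <= lim & !(peps %in% ambiguous_seqs))
    if (length(ok)) {
      pick <- ok[sample_int(rng, length(ok),
                            min(decoys_per_locus, length(ok)))]
      for (p in pick) add(peps[p], "decoy", gid, paste0(gid, ".1"))
    }
  }
  for (amb in sim$ambiguous)
    add(amb$sequence, "ambiguous", amb$gene_a, NA_character_)
  ledger <- do.call(rbind, rows)
  list(records = ledger[, c("sequence", "confidence")], ledger = ledger)
}

# plant one tryptic peptide of locus A into locus B's first coding exon,
# flanked by K and G codons so it digests out of both proteomes
plant_ambiguous_peptide <- function(genome, meta_a, meta_b, rng) {
  cod_a <- meta_a$cds_codons
  prot_a <- translate_dna(paste(cod_a, collapse = ""))
  peps <- tryptic_digest(prot_a)
  ends <- cumsum(nchar(peps)); starts <- ends - nchar(peps) + 1L
  ok <- which(nchar(peps) >= 7L & nchar(peps) <= 12L & starts >= 12L &
                ends <= 80L)
  if (!length(ok)) return(NULL)
  p <- ok[sample_int(rng, length(ok), 1L)]
  pep_codons <- cod_a[starts[p]:ends[p]]
  j <- rint(rng, 15L, 40L)                 # residue slot in B's first exon
  insert <- c("AAG", pep_codons, "GGT")
  log_start <- meta_b$c1_cds_start_logical + 3L * (j - 2L)
  len <- 3L * length(insert)
  ins_seq <- paste(insert, collapse = "")
  if (meta_b$strand == "-") {
    gs <- meta_b$contig_len - (log_start + len)
    ins_seq <- revcomp(ins_seq)
  } else gs <- log_start
  contig <- genome[[meta_b$chrom]]
  substr(contig, gs + 1L, gs + len) <- ins_seq
  genome[[meta_b$chrom]] <- contig
  list(genome = genome,
       info = list(sequence = peps[p], gene_a = meta_a$gene_id,
                   gene_b = meta_b$gene_id))
}

#' Simulate a full study: loci, genome, counts, miRNAs and peptides
#'
#' @param n_loci Number of loci.
#' @param design A [design_spec()].
#' @param type_weights Named sampling weights for planted event types
#'   (defaults emulate an event-type mix dominated by alternative
#'   acceptors and intron retention).
#' @param single_fraction Fraction of single-isoform loci.
#' @param multi_fraction Fraction of multi-isoform loci carrying a second
#'   planted event.
#' @param n_mirnas,frac_alternative Passed to [plant_mirna_targets()].
#' @param n_ambiguous_pairs Gene pairs receiving a shared (ambiguous)
#'   peptide.
#' @param frac_low_conf,decoys_per_locus Passed to [make_peptides()].
#' @return A study simulation list: `genes`, `genome`, `events` (planted
#'   ledger), `truth` (per-isoform ORF/NMD truth), `metas`, `abundance`,
#'   `junctions`, `coverage`, `counts_truth`, `mirnas`, `mirna_ledger`,
#'   `peptides`, `peptide_ledger`, `proteome`, `design`.
#' @export
simulate_study <- function(n_loci = 60L, design = design_spec(),
                           type_weights = c(AltA = 0.38, IR = 0.30,
                                            AltD = 0.12, ES = 0.08,
                                            AltFirst = 0.07, AltLast = 0.05),
                           single_fraction = 0.25, multi_fraction = 0.1,
                           n_mirnas = 12L, frac_alternative = 0.6,
                           n_ambiguous_pairs = 2L, frac_low_conf = 0.2,
                           decoys_per_locus = 1L) {
  rng <- make_rng(design$seed)
  genes <- list(); genome <- character(); metas <- list()
  ev_rows <- list()
  for (i in seq_len(n_loci)) {
    gid <- sprintf("G%04d", i)
    strand <- sample_vec(rng, c("+", "-"), 1L)
    types <- if (rbern(rng, 1L, single_fraction)) character() else {
      t1 <- rng_eval(rng, sample(names(type_weights), 1L,
                                 prob = type_weights))
      others <- setdiff(names(type_weights), t1)
      if (length(others) && rbern(rng, 1L, multi_fraction))
        c(t1, sample_vec(rng, others, 1L))
      else t1
    }
    lseed <- (design$seed %% 100000L) * 20011L + i
    loc <- make_locus(locus_spec(types, seed = lseed), gene_id = gid,
                      strand = strand)
    genes[[gid]] <- loc$gene
    genome <- c(genome, loc$genome)
    metas[[gid]] <- loc$meta
    if (nrow(loc$events)) ev_rows[[length(ev_rows) + 1L]] <- loc$events
  }
  sim <- list(genes = genes, genome = genome, metas = metas,
              events = if (length(ev_rows)) do.call(rbind, ev_rows) else NULL,
              design = design)

  # ambiguous peptides: copy a tryptic peptide between gene pairs
  sim$ambiguous <- list()
  pool <- sample_vec(rng, names(metas), length(metas))
  n_pairs <- min(n_ambiguous_pairs, length(pool) %/% 2L)
  if (n_pairs > 0L) {
    for (k in seq_len(n_pairs)) {
      pair <- pool[c(2L * k - 1L, 2L * k)]
      res <- plant_ambiguous_peptide(sim$genome, metas[[pair[1]]],
                                     metas[[pair[2]]], rng)
      if (!is.null(res)) {
        sim$genome <- res$genome
        sim$ambiguous[[length(sim$ambiguous) + 1L]] <- res$info
      }
    }
  }

  mir <- plant_mirna_targets(sim, n_mirnas = n_mirnas, seed = design$seed,
                             frac_alternative = frac_alternative)
  sim$genome <- mir$genome
  sim$mirnas <- mir$mirnas
  sim$mirna_ledger <- mir$ledger

  # ground truth recomputed on the final genome
  truth <- lapply(names(genes), function(gid)
    locus_truth(genes[[gid]], sim$genome, metas[[gid]]$cds_boundary))
  sim$truth <- do.call(rbind, truth)
  sim$proteome <- sim$truth[, c("transcript_id", "gene_id", "protein")]

  cl <- vapply(metas, `[[`, integer(1), "contig_len")
  names(cl) <- vapply(metas, `[[`, "", "chrom")
  counts <- simulate_counts(genes, design, contig_lengths = cl)
  sim$abundance <- counts$abundance
  sim$junctions <- counts$junctions
  sim$coverage <- counts$coverage
  sim$counts_truth <- counts$truth

  pep <- make_peptides(sim, seed = design$seed, frac_low = frac_low_conf,
                       decoys_per_locus = decoys_per_locus)
  sim$peptides <- pep$records
  sim$peptide_ledger <- pep$ledger
  sim
}
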