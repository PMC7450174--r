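# Peptide-level validation: digestion, confidence filter, unique mapping,
# junction-spanning evidence.

test_that("tryptic digestion cleaves after K/R but not before P", {
  expect_equal(tryptic_digest("MKR"), c("MK", "R"))
  expect_equal(tryptic_digest("MKPR"), "MKPR")
  expect_equal(tryptic_digest("AAKBBRCC"), c("AAK", "BBR", "CC"))
  expect_equal(tryptic_digest(""), character())
})

test_that("the confidence filter keeps the 95% boundary and drops below", {
  rec <- data.frame(sequence = c("AAK", "CCK", "DDK"),
                    confidence = c(0.95, 0.94, 0.991))
  kept <- filter_peptides(rec)
  expect_setequal(kept$sequence, c("AAK", "DDK"))
  expect_equal(nrow(filter_peptides(rec[0, , drop = FALSE])), 0L)
  expect_error(filter_peptides(data.frame(sequence = "A",
                                          confidence = 1.2)), "confidence")
})

test_that("peptides mapping to two genes are discarded as ambiguous", {
  proteome <- data.frame(
    transcript_id = c("g1.1", "g1.2", "g2.1"),
    gene_id = c("g1", "g1", "g2"),
    protein = c("MAAAKTTTR", "MAAAKGGGR", "CCCAAAKCC"),
    stringsAsFactors = FALSE)
  rec <- data.frame(sequence = c("AAAK", "TTTR", "QQQQ"),
                    confidence = 0.99)
  res <- map_peptides(rec, proteome)
  expect_equal(res$ambiguous, "AAAK")          # in g1 and g2
  expect_equal(res$supports$sequence, "TTTR")  # unique to one isoform
  expect_equal(res$supports$transcript_id, "g1.1")
  expect_equal(res$supports$aa_start, 6L)
  # absent peptide yields no record; isoform-level multi-match is kept
  rec2 <- data.frame(sequence = "MAAAK", confidence = 0.99)
  res2 <- map_peptides(rec2, proteome)
  expect_equal(nrow(res2$supports), 2L)
})

test_that("junction evidence requires complete residues on both sides", {
  # one gene, IR pair; boundary at the exon/retained-intron border
  loc <- make_locus(locus_spec("IR", seed = 13))
  genes <- list(G0001 = loc$gene)
  orfs <- lapply(loc$gene$transcripts, function(tx)
    find_orf(transcript_sequence(tx, loc$genome), 100))
  events <- classify_gene(loc$gene)$events
  tid <- loc$events$isoform_b[loc$events$type == "IR"]
  tx <- loc$gene$transcripts[[tid]]
  orf <- orfs[[tid]]
  reg <- parse_region(events$region[events$type == "IR"])
  b <- if (tx$strand == "+") reg$starts else reg$ends
  t_nt <- transcript_bases_before(tx, b)
  bd_res <- (t_nt - orf$cds_start) %/% 3L     # residues fully 5' of boundary
  prot <- orf$protein
  mk_support <- function(a_start, a_end) data.frame(
    sequence = substr(prot, a_start, a_end), confidence = 0.99,
    gene_id = "G0001", transcript_id = tid,
    aa_start = a_start, aa_end = a_end, stringsAsFactors = FALSE)
  # 4 residues each side: validates
  sup <- mk_support(bd_res - 3L, bd_res + 4L)
  val <- junction_evidence(sup, genes, orfs, events)
  expect_true(nrow(val) >= 1L)
  expect_equal(unique(val$type), "IR")
  expect_true(all(val$overhang_5 >= 1 & val$overhang_3 >= 1))
  # peptide ending exactly at the boundary: 0 overhang on one side
  sup0 <- mk_support(bd_res - 5L, bd_res)
  expect_equal(nrow(junction_evidence(sup0, genes, orfs, events)), 0L)
  # peptide entirely within one exon never validates
  supx <- mk_support(10L, 20L)
  expect_equal(nrow(junction_evidence(supx, genes, orfs, events)), 0L)
  # raising min_overhang only removes validations
  v1 <- nrow(junction_evidence(sup, genes, orfs, events, min_overhang = 1))
  v4 <- nrow(junction_evidence(sup, genes, orfs, events, min_overhang = 4))
  v5 <- nrow(junction_evidence(sup, genes, orfs, events, min_overhang = 5))
  expect_true(v4 <= v1)
  expect_equal(v5, 0L)
})

test_that("the three criteria compose into a pure filter chain", {
  sim <- simulate_study(n_loci = 12, design = design_spec(seed = 7),
                        single_fraction = 0, type_weights = c(IR = 1),
                        n_mirnas = 0, frac_low_conf = 0.3)
  orfs <- list()
  for (g in sim$genes) for (tx in g$transcripts)
    orfs[[tx$transcript_id]] <-
      find_orf(transcript_sequence(tx, sim$genome), 100)
  events <- do.call(rbind, lapply(sim$genes,
                                  function(g) classify_gene(g)$events))
  v1 <- validate_isoforms(sim$peptides, sim$proteome, sim$genes, orfs,
                          events, min_conf = 0.95)
  v2 <- validate_isoforms(sim$peptides, sim$proteome, sim$genes, orfs,
                          events, min_conf = 0.99)
  expect_true(nrow(v2$validated) <= nrow(v1$validated))
  expect_true(all(v2$validated$sequence %in% v1$validated$sequence))
  # precision: every validated peptide is a planted junction peptide
  led <- sim$peptide_ledger
  jk <- paste(led$gene_id[led$class == "junction"],
              led$sequence[led$class == "junction"])
  expect_true(all(paste(v1$validated$gene_id,
                        v1$validated$sequence) %in% jk))
  # recall equals the confident planted fraction
  hi <- led$class == "junction" & led$confidence >= 0.95
  expect_true(all(paste(led$gene_id[hi], led$sequence[hi]) %in%
                    paste(v1$validated$gene_id, v1$validated$sequence)))
})
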