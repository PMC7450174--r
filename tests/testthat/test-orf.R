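# ORF prediction, NMD rules, domain projection.

test_that("find_orf handles toy sequences, no-ORF and ambiguity verdicts", {
  o <- find_orf("ATGAAATAG", min_len_aa = 2)
  expect_equal(o$verdict, "ok")
  expect_equal(o$protein, "MK")
  expect_equal(o$cds_start, 0L)
  expect_equal(o$cds_stop, 6L)
  expect_equal(find_orf(strrep("C", 60))$verdict, "none")
  # two equal-length non-overlapping ORFs tie
  two <- paste0("ATGAAATAG", "C", "ATGGGGTAA")
  expect_equal(find_orf(two, min_len_aa = 2)$verdict, "ambiguous")
  # runner-up within the configured ratio is also ambiguous
  near <- paste0("ATGAAAAAAGACTAG", "C", "ATGGGGGGGTAA")
  expect_equal(find_orf(near, min_len_aa = 2)$verdict, "ok")
  expect_equal(find_orf(near, min_len_aa = 2,
                        ambiguity_ratio = 0.7)$verdict, "ambiguous")
  expect_error(find_orf("ATGXXXTAG"), "non-ACGTN")
})

test_that("find_orf agrees with the brute-force three-frame oracle", {
  set.seed(8)
  for (i in 1:150) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:300, 1), TRUE),
               collapse = "")
    lens <- oracle_find_orf_lengths(s, 3L)
    o <- find_orf(s, min_len_aa = 3)
    if (length(lens) == 0) {
      expect_equal(o$verdict, "none", info = s)
    } else if (length(lens) >= 2 && lens[1] == lens[2]) {
      expect_equal(o$verdict, "ambiguous", info = s)
    } else {
      expect_equal(o$verdict, "ok", info = s)
      expect_equal(nchar(o$protein), lens[1], info = s)
      expect_equal(o$n_candidates, length(lens), info = s)
    }
  }
})

nmd_toy <- function(utr3_len, exon2_utr = 0) {
  # CDS of 150 nt starting at 10; optional second exon entirely 3'UTR
  L1 <- 10 + 150 + utr3_len - exon2_utr
  starts <- c(0L)
  ends <- c(L1)
  if (exon2_utr > 0) { starts <- c(0L, L1 + 100L); ends <- c(L1, L1 + 100L + exon2_utr) }
  tx <- transcript_model("t", "g", "c", "+", starts, ends)
  orf <- list(verdict = "ok", cds_start = 10L, cds_stop = 10L + 147L)
  list(tx = tx, orf = orf)
}

test_that("NMD rules use strict thresholds at 350 nt and 55 nt", {
  x <- nmd_toy(351)
  v <- nmd_call(x$tx, x$orf)
  expect_equal(v$utr3_len, 351)
  expect_true(v$rule_long_utr3)
  expect_true(v$nmd_candidate)
  x <- nmd_toy(350)
  v <- nmd_call(x$tx, x$orf)
  expect_false(v$rule_long_utr3)
  expect_false(v$nmd_candidate)        # single exon: no junction rule
  expect_equal(v$stop_to_last_junction, -Inf)
  # stop 56 nt upstream of the last junction triggers rule (b)
  x <- nmd_toy(100, exon2_utr = 47)    # junction at offset stop + 56
  v <- nmd_call(x$tx, x$orf)
  expect_equal(v$stop_to_last_junction, 56)
  expect_true(v$rule_junction_distance)
  expect_true(v$nmd_candidate)
  x <- nmd_toy(100, exon2_utr = 48)    # junction at stop + 55: not NMD
  v <- nmd_call(x$tx, x$orf)
  expect_equal(v$stop_to_last_junction, 55)
  expect_false(v$nmd_candidate)
  expect_error(nmd_call(nmd_toy(0)$tx,
                        list(cds_start = 10L, cds_stop = 160L)),
               "beyond transcript end")
})

test_that("NMD rules are monotone in UTR extension and intron addition", {
  for (u in c(100, 300, 340, 360, 500)) {
    v1 <- with(nmd_toy(u), nmd_call(tx, orf))
    v2 <- with(nmd_toy(u + 60), nmd_call(tx, orf))
    expect_true(v2$rule_long_utr3 >= v1$rule_long_utr3)
  }
  for (e2 in c(10, 40, 50, 80)) {
    v1 <- with(nmd_toy(200, e2), nmd_call(tx, orf))
    # appending a further downstream exon moves the last junction 3'
    x <- nmd_toy(200, e2)
    L <- x$tx$exon_ends[2]
    tx2 <- transcript_model("t", "g", "c", "+",
                            c(x$tx$exon_starts, L + 50L),
                            c(x$tx$exon_ends, L + 80L))
    v2 <- nmd_call(tx2, x$orf)
    expect_true(v2$rule_junction_distance >= v1$rule_junction_distance)
  }
})

domain_toy <- function() {
  # two-exon gene, CDS spans both exons; variant skips part of exon 2
  genome <- NULL
  primary <- transcript_model("p", "g", "c", "+", c(0, 400), c(300, 700))
  # CDS: offsets 0..599 on primary (200 codons, stop not modeled here)
  orf_p <- list(verdict = "ok", cds_start = 0L, cds_stop = 597L,
                protein = strrep("A", 199))
  list(primary = primary, orf_p = orf_p)
}

test_that("domain projection distinguishes retained, truncated and lost", {
  d <- domain_toy()
  # identical variant: all retained
  variant <- transcript_model("v", "g", "c", "+", c(0, 400), c(300, 700))
  orf_v <- d$orf_p
  doms <- data.frame(name = c("D1", "D2"), start_aa = c(10, 120),
                     end_aa = c(60, 180))
  arr <- project_domains(d$primary, d$orf_p, variant, orf_v, doms)
  expect_equal(arr$status, c("retained", "retained"))
  # variant losing most of D1's coding exon bases (an in-frame 240-nt
  # deletion): D1 lost, downstream in-frame domain retained
  v2 <- transcript_model("v2", "g", "c", "+", c(0, 400), c(60, 700))
  orf_v2 <- list(verdict = "ok", cds_start = 0L, cds_stop = 357L)
  arr2 <- project_domains(d$primary, d$orf_p, v2, orf_v2, doms)
  expect_equal(arr2$status[1], "lost")       # only codons 10..20 remain
  expect_equal(arr2$status[2], "retained")   # in frame beyond the loss
  expect_true(arr2$codons_in_frame[1] < 0.5)
  # a variant whose reading frame is shifted upstream loses everything
  orf_v3 <- list(verdict = "ok", cds_start = 1L, cds_stop = 595L)
  arr3 <- project_domains(d$primary, d$orf_p, variant, orf_v3, doms)
  expect_equal(arr3$status, c("lost", "lost"))
  expect_error(project_domains(d$primary, d$orf_p, variant, orf_v,
                               data.frame(name = "X", start_aa = 1,
                                          end_aa = 500)),
               "outside the primary protein")
})

test_that("novel-isoform screen needs a retained domain and a changed arrangement", {
  prim <- data.frame(name = c("basic", "HLH"), start_aa = c(1, 30),
                     end_aa = c(20, 80),
                     status = c("retained", "retained"))
  lost_all <- transform(prim, status = c("lost", "lost"))
  bhlh_like <- transform(prim, status = c("lost", "retained"))
  same <- prim
  res <- novel_isoform_screen(prim, list(v1 = lost_all, v2 = bhlh_like,
                                         v3 = same))
  expect_false(res$report$novel_candidate[1])   # nothing retained
  expect_true(res$report$novel_candidate[2])    # dimerizes, can't bind DNA
  expect_false(res$report$novel_candidate[3])   # identical arrangement
  expect_true(res$flagged)
})
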