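# Synthetic-data generators: determinism, planted ground truth, noise
# model marginals.

test_that("locus generation is a pure function of the seed", {
  a <- make_locus(locus_spec(c("IR", "AltA"), seed = 77), strand = "-")
  b <- make_locus(locus_spec(c("IR", "AltA"), seed = 77), strand = "-")
  expect_identical(a$genome, b$genome)
  expect_identical(a$gene, b$gene)
  expect_identical(a$events, b$events)
  c <- make_locus(locus_spec(c("IR", "AltA"), seed = 78), strand = "-")
  expect_false(identical(a$genome, c$genome))
})

test_that("invalid locus specs are rejected", {
  expect_error(locus_spec(c("IR", "IR")), "duplicated")
  expect_error(locus_spec("MutuallyExclusive"), "unknown event type")
  expect_error(locus_spec("IR", intron_len = c(5, 50)), "minimum intron")
})

test_that("planted isoform structure matches the requested events", {
  loc <- make_locus(locus_spec(c("IR", "ES"), seed = 5))
  expect_length(loc$gene$transcripts, 3L)      # primary + chained variants
  expect_setequal(loc$events$type, c("IR", "ES"))
  # the IR variant (and only it) is a planted NMD target
  ir_iso <- loc$events$isoform_b[loc$events$type == "IR"]
  expect_true(loc$truth$nmd[loc$truth$transcript_id == ir_iso])
  expect_false(any(loc$truth$nmd[loc$truth$transcript_id != ir_iso]))
  # planted NMD comes with a premature stop: a long 3'UTR
  expect_true(loc$truth$utr3_len[loc$truth$transcript_id == ir_iso] > 350)
})

test_that("whole-study simulation is deterministic under the seed", {
  s1 <- simulate_study(n_loci = 6, design = design_spec(seed = 19),
                       n_mirnas = 4)
  s2 <- simulate_study(n_loci = 6, design = design_spec(seed = 19),
                       n_mirnas = 4)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$peptides, s2$peptides)
  expect_identical(s1$mirnas, s2$mirnas)
})

test_that("zero depth silences junction support and coverage", {
  genes <- list(G1 = make_locus(locus_spec("ES", seed = 2),
                                gene_id = "G1")$gene)
  cnt <- simulate_counts(genes, design_spec(seed = 2, depth = 0))
  expect_true(all(cnt$junctions$read_support == 0))
  expect_true(all(cnt$coverage[[1]]$depth == 0))
})

test_that("a single-isoform gene has proportion one everywhere", {
  genes <- list(G1 = make_locus(locus_spec(character(), seed = 2),
                                gene_id = "G1")$gene)
  cnt <- simulate_counts(genes, design_spec(seed = 2))
  pr <- proportions(cnt$abundance, "G1")
  expect_true(all(pr$profiles[[paste0("p_", "G1.1")]] == 1))
})

test_that("junction support means track the Poisson intensity", {
  # a single-isoform gene has share 1 at every junction, so pooled
  # supports are Poisson(depth); check the sample mean at n >= 100
  loc <- make_locus(locus_spec(character(), seed = 31), gene_id = "G1")
  sup <- unlist(lapply(1:25, function(s) {
    simulate_counts(list(G1 = loc$gene),
                    design_spec(seed = s, depth = 30))$junctions$read_support
  }))
  expect_true(length(sup) >= 100)
  se <- sqrt(30 / length(sup))
  expect_true(abs(mean(sup) - 30) < 4 * se)
})

test_that("planted proportion shifts are recovered by estimation", {
  genes <- lapply(1:40, function(i)
    make_locus(locus_spec("IR", seed = 900 + i),
               gene_id = sprintf("G%02d", i))$gene)
  names(genes) <- sprintf("G%02d", 1:40)
  d <- design_spec(seed = 41, differential_fraction = 1, delta = 0.3,
                   sigma = 0.2)
  cnt <- simulate_counts(genes, d)
  grid <- condition_labels(d)
  ctrl <- grid$condition[grid$treatment == "mock"]
  trt <- grid$condition[grid$treatment == "MeJA"]
  shifts <- vapply(names(genes), function(g) {
    pr <- proportions(cnt$abundance, g)$profiles
    p1 <- pr[[grep("^p_", names(pr), value = TRUE)[1]]]
    mean(p1[pr$condition %in% ctrl]) - mean(p1[pr$condition %in% trt])
  }, numeric(1))
  se <- stats::sd(shifts) / sqrt(length(shifts))
  expect_true(abs(mean(shifts) - 0.3) < 3 * se + 0.02)
})

test_that("peptide generation digests by the tryptic rule and plants evidence", {
  sim <- simulate_study(n_loci = 8, design = design_spec(seed = 23),
                        single_fraction = 0, type_weights = c(IR = 1),
                        n_mirnas = 0)
  led <- sim$peptide_ledger
  expect_true(all(c("junction", "decoy") %in% led$class))
  # every emitted peptide is a tryptic fragment of its source protein
  for (i in which(led$class != "ambiguous")) {
    tid <- led$transcript_id[i]
    prot <- sim$proteome$protein[sim$proteome$transcript_id == tid]
    expect_true(led$sequence[i] %in% tryptic_digest(prot),
                info = led$sequence[i])
  }
  # ambiguous peptides occur in two genes' proteomes
  for (amb in sim$ambiguous) {
    hits <- unique(sim$proteome$gene_id[
      grepl(amb$sequence, sim$proteome$protein, fixed = TRUE)])
    expect_true(length(hits) >= 2)
  }
})
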