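# miRNA target scanning and AS-coupled classification.

rc_rna <- function(m) chartr("T", "U", revcomp(chartr("U", "T", m)))

test_that("a planted perfect complement scores expectation zero", {
  set.seed(5)
  m <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  site <- rc_rna(m)
  tx_seq <- paste0(strrep("C", 50), chartr("U", "T", site), strrep("C", 30))
  hits <- scan_targets(tx_seq, c(mirX = m))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$start, 50L)
  expect_equal(hits$end, 71L)
})

test_that("a single mismatch at a seed position costs twice the penalty", {
  m <- paste(rep(c("A", "C", "G", "U"), len = 21), collapse = "")
  site <- rc_rna(m)
  # mutate the target base pairing miRNA position 5 (inside seed 2-13)
  v <- strsplit(site, "")[[1]]
  j <- 21 - 5 + 1
  v[j] <- setdiff(c("A", "C", "G", "U"),
                  c(v[j], switch(substr(m, 5, 5), A = "G", C = "U",
                                 G = "A", U = "C")))[1]
  tx_seq <- chartr("U", "T", paste(v, collapse = ""))
  hits <- scan_targets(tx_seq, c(mirX = m), mirna_config(cutoff = 10))
  expect_equal(hits$expectation, 2)
  # wobble costs half a mismatch, doubled in seed
  v2 <- strsplit(site, "")[[1]]
  mb <- substr(m, 5, 5)
  v2[j] <- if (mb == "G") "U" else if (mb == "U") "G" else v2[j]
  if (v2[j] != strsplit(site, "")[[1]][j]) {
    h2 <- scan_targets(chartr("U", "T", paste(v2, collapse = "")),
                       c(mirX = m), mirna_config(cutoff = 10))
    expect_equal(h2$expectation, 1)
  }
})

test_that("scanner equals the exhaustive per-window penalty oracle", {
  set.seed(17)
  for (rep in 1:5) {
    tx_seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    m <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    cfg <- mirna_config(cutoff = 22)
    hits <- scan_targets(tx_seq, c(m1 = m), cfg)
    pen <- vapply(1:(200 - 21 + 1), function(p)
      oracle_site_penalty(tx_seq, m, p), numeric(1))
    # every reported site's expectation matches the oracle at its start
    for (i in seq_len(nrow(hits)))
      expect_equal(hits$expectation[i], pen[hits$start[i] + 1])
    # the best reported site is the global oracle optimum
    expect_equal(min(hits$expectation), min(pen))
    # nothing under the cutoff is missed entirely
    cfg2 <- mirna_config(cutoff = min(pen) - 0.25)
    expect_equal(nrow(scan_targets(tx_seq, c(m1 = m), cfg2)), 0L)
  }
})

test_that("lowering the cutoff never adds sites", {
  set.seed(23)
  tx_seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  m <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  prev <- Inf
  for (cut in c(25, 18, 12, 6, 3)) {
    n <- nrow(scan_targets(tx_seq, c(m1 = m), mirna_config(cutoff = cut)))
    expect_true(n <= prev)
    prev <- n
  }
})

test_that("planted alternative-region sites are AS-coupled; shared sites are not", {
  sim <- simulate_study(n_loci = 16, design = design_spec(seed = 11),
                        single_fraction = 0, type_weights = c(IR = 1),
                        n_mirnas = 8, frac_alternative = 0.5)
  sites <- scan_gene_targets(sim$genes, sim$genome, sim$mirnas)
  for (i in seq_len(nrow(sim$mirna_ledger))) {
    led <- sim$mirna_ledger[i, ]
    gene <- sim$genes[[led$gene_id]]
    ev <- sim$events[sim$events$gene_id == led$gene_id, , drop = FALSE]
    cp <- coupled_as_mirna(gene, ev,
                           sites[sites$gene_id == led$gene_id, ,
                                 drop = FALSE])
    row <- cp$by_mirna[cp$by_mirna$mirna_id == led$mirna_id, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$as_coupled, led$in_alternative_region,
                 info = paste(led$mirna_id, led$gene_id))
    # perfect planted site is reported with expectation zero
    s <- sites[sites$gene_id == led$gene_id &
                 sites$mirna_id == led$mirna_id, ]
    expect_true(any(s$expectation == 0))
  }
})

test_that("two miRNAs on one transcript raise the multi-site flag", {
  set.seed(31)
  m1 <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  m2 <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  body <- paste0(strrep("C", 40), chartr("U", "T", rc_rna(m1)),
                 strrep("C", 20), chartr("U", "T", rc_rna(m2)),
                 strrep("C", 40))
  genome <- c(c1 = body)
  tx <- transcript_model("g1.1", "g1", "c1", "+", 0, nchar(body))
  gene <- gene_model("g1", list(tx))
  sites <- scan_gene_targets(list(g1 = gene), genome,
                             c(mirA = m1, mirB = m2))
  cp <- coupled_as_mirna(gene, classify_gene(gene)$events, sites)
  expect_true(cp$multi_site)
  expect_false(cp$as_coupled)
})
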