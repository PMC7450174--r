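# Isoform proportions, sqrt-JSD and the permutation test.

toy_table <- function(abund) {
  # abund: list of condition -> list of replicate vectors (t1, t2)
  rows <- list()
  for (cond in names(abund)) for (r in seq_along(abund[[cond]])) {
    a <- abund[[cond]][[r]]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = paste0("t", seq_along(a)), gene_id = "g1",
      condition = cond, replicate = r, abundance = a,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("proportions normalize per sample and flag zero totals", {
  tab <- toy_table(list(A = list(c(10, 0), c(5, 5)), B = list(c(0, 0))))
  pr <- proportions(tab, "g1")
  expect_equal(pr$profiles$p_t1, c(1, 0.5))
  expect_equal(pr$profiles$p_t2, c(0, 0.5))
  expect_equal(nrow(pr$excluded), 1L)      # the all-zero sample
  expect_equal(pr$excluded$condition, "B")
  expect_error(proportions(tab, "missing"), "absent")
})

test_that("js_distance has exact endpoints and matches the KL oracle", {
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(js_distance(c(0.5, 0.5), c(0.75, 0.25)),
               oracle_sqrt_jsd(c(0.5, 0.5), c(0.75, 0.25)))
  set.seed(12)
  for (i in 1:20) {
    p <- rgamma(3, 1); p <- p / sum(p)
    q <- rgamma(3, 1); q <- q / sum(q)
    r <- rgamma(3, 1); r <- r / sum(r)
    expect_equal(js_distance(p, q), oracle_sqrt_jsd(p, q))
    expect_equal(js_distance(p, q), js_distance(q, p))  # symmetry
    expect_true(js_distance(p, q) >= 0 && js_distance(p, q) <= 1)
    # triangle inequality spot-check (sqrt-JSD is a metric)
    expect_true(js_distance(p, r) <=
                  js_distance(p, q) + js_distance(q, r) + 1e-12)
  }
  expect_error(js_distance(c(1, 0), c(1, 0, 0)), "length")
  expect_error(js_distance(c(0.5, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("the permutation test respects its resolution floor", {
  tab <- toy_table(list(
    A = list(c(9, 1), c(8, 2), c(10, 1)),
    B = list(c(2, 8), c(1, 9), c(2, 9))))
  res <- diff_splicing_test(tab, c("A", "B"), seed = 4)
  expect_equal(res$n_perm_used, 19L)       # 3v3: choose(6,3) - identity
  expect_equal(res$min_attainable_p, 1 / 20)
  # the mirror labelling always ties, so p can never reach 1/20
  expect_true(res$p_value >= 2 / 20)
  expect_true(res$statistic > 0.5)         # strongly shifted proportions
  expect_error(diff_splicing_test(
    toy_table(list(A = list(c(1, 1)), B = list(c(1, 1), c(1, 1)))),
    c("A", "B")), "fewer than 2")
})

test_that("q-values are BH-monotone and never below their p-values", {
  set.seed(6)
  design <- design_spec(seed = 6, differential_fraction = 0.5)
  sim_counts <- simulate_counts(
    lapply(sprintf("G%02d", 1:12), function(gid) {
      loc <- make_locus(locus_spec("IR", seed = match(gid,
        sprintf("G%02d", 1:12))), gene_id = gid)
      loc$gene
    }), design)
  grid <- condition_labels(design)
  contrast <- unique(grid$condition)[1:2]
  res <- diff_splicing_test(sim_counts$abundance, contrast, seed = 6)
  expect_true(all(res$q_value >= res$p_value))
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  expect_true(all(res$statistic >= 0 & res$statistic <= 1))
})

test_that("planted proportion shifts separate from null loci in distribution", {
  genes <- lapply(sprintf("G%02d", 1:30), function(gid) {
    loc <- make_locus(locus_spec("AltA",
      seed = 500 + match(gid, sprintf("G%02d", 1:30))), gene_id = gid)
    loc$gene
  })
  d_null <- design_spec(seed = 9, differential_fraction = 0)
  d_alt <- design_spec(seed = 9, differential_fraction = 1, delta = 0.5)
  cn <- simulate_counts(genes, d_null)
  ca <- simulate_counts(genes, d_alt)
  grid <- condition_labels(d_null)
  contrast <- grid$condition[grid$genotype == "WT" &
                               grid$tissue == "shoot"][1:2]
  s_null <- diff_splicing_test(cn$abundance, contrast, seed = 1)$statistic
  s_alt <- diff_splicing_test(ca$abundance, contrast, seed = 1)$statistic
  expect_true(median(s_alt) > median(s_null))
  expect_true(mean(s_alt) > mean(s_null) + 0.1)
})

test_that("expression ratios follow the treated/control convention", {
  tab <- toy_table(list(A = list(c(5, 5), c(5, 5)),
                        B = list(c(10, 10), c(10, 10))))
  r <- expression_ratio_matrix(tab, c("A", "B"))
  expect_equal(r$ratio, 2)               # 20 vs 10, no pseudo-abundance
  expect_equal(r$log2_ratio, 1)
  tab0 <- toy_table(list(A = list(c(0, 0), c(0, 0)),
                         B = list(c(5, 5), c(5, 5))))
  r0 <- expression_ratio_matrix(tab0, c("A", "B"), pseudo = 1)
  expect_equal(r0$ratio, 11)             # (10 + 1) / (0 + 1)
  r1 <- expression_ratio_matrix(tab, c("B", "A"))
  expect_equal(r1$ratio, 0.5)
})

test_that("null permutation p-values are calibrated at attainable levels", {
  # 3v3 label permutation has 19 non-identity assignments in 10 mirror
  # pairs, so attainable p-values are {2, 4, ..., 20}/20 and the exact
  # test is calibrated at multiples of 0.1
  genes <- lapply(sprintf("N%03d", 1:200), function(gid)
    gene_model(gid, list(
      transcript_model(paste0(gid, ".1"), gid, paste0("c_", gid), "+",
                       c(0, 200), c(100, 300)),
      transcript_model(paste0(gid, ".2"), gid, paste0("c_", gid), "+",
                       0, 300))))
  names(genes) <- sprintf("N%03d", 1:200)
  d <- design_spec(genotypes = "WT", tissues = "shoot",
                   differential_fraction = 0, seed = 77L)
  cnt <- simulate_counts(genes, d)
  res <- diff_splicing_test(cnt$abundance,
                            unique(cnt$abundance$condition), seed = 77L)
  expect_true(all(res$p_value >= 2 / 20))
  for (alpha in c(0.1, 0.3, 0.5)) {
    emp <- mean(res$p_value <= alpha + 1e-12)
    se <- sqrt(alpha * (1 - alpha) / 200)
    expect_true(abs(emp - alpha) < 3.5 * se + 0.01,
                info = paste("alpha", alpha, "empirical", emp))
  }
})
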