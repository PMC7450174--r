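# Independent brute-force oracles used to cross-check the package
# implementations on small instances. These work on per-base vectors and
# naive scans, deliberately avoiding the interval algebra of the package.

# --- per-base AS classification oracle ---------------------------------

oracle_membership <- function(tx, lo, hi) {
  mem <- rep(FALSE, hi - lo)
  for (i in seq_along(tx$exon_starts)) {
    idx <- which(seq(lo, hi - 1L) >= tx$exon_starts[i] &
                 seq(lo, hi - 1L) < tx$exon_ends[i])
    mem[idx] <- TRUE
  }
  mem
}

oracle_mem3 <- function(tx, mem_vec, lo, p) {
  span_lo <- tx$exon_starts[1L]
  span_hi <- tx$exon_ends[length(tx$exon_ends)]
  if (p < span_lo || p >= span_hi) return("O")
  if (mem_vec[p - lo + 1L]) "E" else "I"
}

oracle_classify_pair <- function(a, b) {
  lo <- min(a$exon_starts[1L], b$exon_starts[1L]) - 2L
  hi <- max(a$exon_ends[length(a$exon_ends)],
            b$exon_ends[length(b$exon_ends)]) + 2L
  memA <- oracle_membership(a, lo, hi)
  memB <- oracle_membership(b, lo, hi)
  dif <- memA != memB
  if (!any(dif)) return(data.frame(type = character(),
                                   region = character()))
  # maximal runs of differing bases
  r <- rle(dif)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = lo + starts[r$values] - 1L,
                     end = lo + ends[r$values])
  # shared splice sites (same role in both transcripts)
  ka <- length(a$exon_starts); kb <- length(b$exon_starts)
  donors_a <- if (ka > 1L) a$exon_ends[-ka] else integer()
  donors_b <- if (kb > 1L) b$exon_ends[-kb] else integer()
  acc_a <- if (ka > 1L) a$exon_starts[-1L] else integer()
  acc_b <- if (kb > 1L) b$exon_starts[-1L] else integer()
  shared <- sort(c(intersect(donors_a, donors_b), intersect(acc_a, acc_b)))
  grp <- 1L
  runs$grp <- NA_integer_
  runs$grp[1L] <- 1L
  if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
    if (any(shared >= runs$end[i - 1L] & shared <= runs$start[i]))
      grp <- grp + 1L
    runs$grp[i] <- grp
  }
  a_lo <- a$exon_starts[1L]; b_lo <- b$exon_starts[1L]
  a_hi <- a$exon_ends[length(a$exon_ends)]
  b_hi <- b$exon_ends[length(b$exon_ends)]
  out <- list()
  for (g in unique(runs$grp)) {
    rs <- runs[runs$grp == g, , drop = FALSE]
    s0 <- rs$start[1L]; e0 <- rs$end[nrow(rs)]
    left_t <- a_lo != b_lo && s0 == min(a_lo, b_lo)
    right_t <- a_hi != b_hi && e0 == max(a_hi, b_hi)
    uniformA <- all(memA[(rs$start[1L] - lo + 1L):(rs$end[nrow(rs)] - lo)] |
                      !dif[(rs$start[1L] - lo + 1L):(rs$end[nrow(rs)] - lo)])
    type <- "Complex"
    if (left_t && right_t) {
      type <- "Complex"
    } else if (left_t) {
      type <- if (a$strand == "+") "AltFirst" else "AltLast"
    } else if (right_t) {
      type <- if (a$strand == "+") "AltLast" else "AltFirst"
    } else if (nrow(rs) == 1L) {
      seg <- (rs$start[1L] - lo + 1L):(rs$end[1L] - lo)
      ownA <- all(memA[seg]); ownB <- all(memB[seg])
      if (ownA || ownB) {
        fl <- c(oracle_mem3(a, memA, lo, rs$start[1L] - 1L),
                oracle_mem3(b, memB, lo, rs$start[1L] - 1L))
        fr <- c(oracle_mem3(a, memA, lo, rs$end[1L]),
                oracle_mem3(b, memB, lo, rs$end[1L]))
        if (all(fl == "E") && all(fr == "E")) type <- "IR"
        else if (all(fl == "I") && all(fr == "I")) type <- "ES"
        else if (all(fl == "I") && all(fr == "E"))
          type <- if (a$strand == "+") "AltA" else "AltD"
        else if (all(fl == "E") && all(fr == "I"))
          type <- if (a$strand == "+") "AltD" else "AltA"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      type = type,
      region = paste(sprintf("%d-%d", rs$start, rs$end), collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# random 2-isoform loci over a shared site grid (<= 6 exons each)
random_transcript_pair <- function(seed) {
  set.seed(seed)
  strand <- sample(c("+", "-"), 1L)
  grid <- sort(sample(seq(0L, 400L, by = 4L), 16L))
  mk <- function(id) {
    k <- sample(1:6, 1L)
    bnd <- sort(sample(grid, 2L * k))
    transcript_model(id, "G", "c", strand,
                     bnd[seq(1L, 2L * k, by = 2L)],
                     bnd[seq(2L, 2L * k, by = 2L)])
  }
  list(a = mk("t1"), b = mk("t2"))
}

# --- brute-force ORF oracle --------------------------------------------

oracle_find_orf_lengths <- function(seq, min_len_aa) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  best <- integer()
  for (s in seq_len(max(0L, n - 5L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    # only the 5'-most ATG after the previous in-frame stop counts
    prev_stop <- FALSE
    p <- s - 3L
    while (p >= 1L) {
      cod <- substr(seq, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) { prev_stop <- TRUE; break }
      if (cod == "ATG") break
      p <- p - 3L
    }
    if (p >= 1L && !prev_stop) next
    p <- s + 3L
    while (p + 2L <= n) {
      cod <- substr(seq, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- (p - s) %/% 3L
        if (len >= min_len_aa) best <- c(best, len)
        break
      }
      p <- p + 3L
    }
  }
  sort(best, decreasing = TRUE)
}

# --- naive miRNA penalty oracle ----------------------------------------

oracle_site_penalty <- function(target_rna, mirna, pos,
                                seed_from = 2L, seed_to = 13L,
                                seed_mult = 2, wobble = 0.5, mismatch = 1) {
  t <- strsplit(toupper(chartr("T", "U", target_rna)), "")[[1]]
  m <- strsplit(toupper(mirna), "")[[1]]
  n <- length(m)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  total <- 0
  for (j in seq_len(n)) {
    tb <- t[pos + (n - j)]
    pen <- if (tb == comp[[m[j]]]) 0
           else if ((m[j] == "G" && tb == "U") ||
                    (m[j] == "U" && tb == "G")) wobble else mismatch
    w <- if (j >= seed_from && j <= seed_to) seed_mult else 1
    total <- total + w * pen
  }
  total
}

# --- direct JSD evaluation ---------------------------------------------

oracle_sqrt_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(x, y) {
    s <- 0
    for (i in seq_along(x)) if (x[i] > 0) s <- s + x[i] * log2(x[i] / y[i])
    s
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}
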