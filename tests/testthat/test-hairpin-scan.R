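test_that("homology seeding finds planted matures with the right coordinates", {
  set.seed(41)
  chrom <- rand_seq(5000)
  mature <- rand_seq(21)
  genome <- c(chr1 = paste0(substr(chrom, 1, 1000), mature,
                            substr(chrom, 1022, 5000)))
  refs <- c(ref1 = mature)
  s <- seed_by_homology(genome, refs, max_mismatches = 0)
  fwd <- s[s$strand == "+", ]
  expect_true(any(fwd$start == 1000 & fwd$end == 1021))
})

test_that("seeding agrees with a brute-force Hamming scan", {
  set.seed(42)
  genome <- c(chrA = rand_seq(800))
  refs <- c(r1 = rand_seq(18), r2 = rand_seq(21))
  s <- seed_by_homology(genome, refs, max_mismatches = 3)
  gch <- strsplit(genome[["chrA"]], "")[[1L]]
  brute <- list()
  for (rid in names(refs)) for (strand in c("+", "-")) {
    pat <- if (strand == "+") refs[[rid]] else revcomp(refs[[rid]])
    pch <- strsplit(pat, "")[[1L]]
    L <- length(pch)
    for (p in seq_len(length(gch) - L + 1L)) {
      mm <- sum(gch[p:(p + L - 1L)] != pch)
      if (mm <= 3) brute[[length(brute) + 1L]] <- c(rid, strand, p - 1L, mm)
    }
  }
  expect_equal(nrow(s), length(brute))
  if (length(brute)) {
    bd <- as.data.frame(do.call(rbind, brute), stringsAsFactors = FALSE)
    got <- paste(s$mirna_id, s$strand, s$start, s$mismatches)
    want <- paste(bd[[1]], bd[[2]], bd[[3]], bd[[4]])
    expect_setequal(got, want)
  }
  # a mature absent everywhere yields nothing
  far <- c(r3 = paste(rep("A", 21), collapse = ""))
  genome_gc <- c(chrB = paste(rep(c("G", "C"), 200), collapse = ""))
  expect_equal(nrow(seed_by_homology(genome_gc, far, max_mismatches = 3)), 0L)
})

test_that("seeding is strand-symmetric and rejects short references", {
  set.seed(43)
  genome <- c(chr1 = rand_seq(600))
  refs <- c(r1 = rand_seq(20))
  s1 <- seed_by_homology(genome, refs, max_mismatches = 3)
  rc_genome <- c(chr1 = revcomp(genome[["chr1"]]))
  s2 <- seed_by_homology(rc_genome, refs, max_mismatches = 3)
  n <- nchar(genome[["chr1"]])
  mirrored <- data.frame(start = n - s2$end, end = n - s2$start,
                         strand = ifelse(s2$strand == "+", "-", "+"))
  expect_setequal(paste(s1$start, s1$end, s1$strand),
                  paste(mirrored$start, mirrored$end, mirrored$strand))
  expect_warning(out <- seed_by_homology(genome, c(short = "ACGTACGTAC")),
                 "short")
  expect_equal(nrow(out), 0L)
})

test_that("inverted-repeat scan matches threshold arithmetic on designed stems", {
  stem10 <- "GCATGCATGC"
  ir <- scan_inverted_repeats(paste0(stem10, "AAAAA", revcomp(stem10)))
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$score, 30)
  expect_equal(ir$identity, 100)
  expect_equal(ir$loop_len, 5L)
  stem8 <- "GCATGCAT"   # 8 x 3 = 24 < 25
  expect_equal(nrow(scan_inverted_repeats(paste0(stem8, "AAAAA", revcomp(stem8)))), 0L)
  expect_equal(nrow(scan_inverted_repeats(strrep("A", 60))), 0L)
})

test_that("scan agrees with the top-down recursion oracle on random windows", {
  set.seed(44)
  p <- ir_params()
  for (k in 1:40) {
    n <- sample(15:40, 1)
    w <- rand_seq(n)
    if (k %% 4 == 0) {   # plant a stem so hits actually occur
      stem <- rand_seq(sample(9:12, 1))
      w <- paste0(substr(w, 1, 3), stem, "AAAA", revcomp(stem),
                  substr(w, 4, nchar(w)))
    }
    got <- scan_inverted_repeats(w, p)
    best <- oracle_ir_best(w, p)
    if (best >= p$threshold) {
      expect_gt(nrow(got), 0)
      expect_equal(max(got$score), best)
    } else {
      expect_equal(nrow(got), 0L)
    }
    expect_gte(best, oracle_ir_gapless(w, p))
  }
})

test_that("reported repeats respect the maximum extent and re-scoring", {
  set.seed(45)
  stem <- rand_seq(150)
  w <- paste0(stem, strrep("A", 80), revcomp(stem))   # extent 380 > 336
  ir <- scan_inverted_repeats(w)
  expect_true(all(ir$right_end - ir$left_start <= 336))
  # perfect-stem score arithmetic: n_pairs * 3 - mismatches... re-derive
  for (r in seq_len(nrow(ir))) {
    matched <- round(ir$n_pairs[r] * ir$identity[r] / 100)
    rescore <- matched * 3 + (ir$n_pairs[r] - matched) * (-4) + ir$n_gaps[r] * (-12)
    expect_equal(rescore, ir$score[r])
  }
})

test_that("windows are centered, clipped and merged with provenance", {
  genome <- c(chr1 = strrep("A", 10000))
  seeds <- data.frame(mirna_id = "m", chrom = "chr1", start = 1000, end = 1021,
                      strand = "+", mismatches = 0, stringsAsFactors = FALSE)
  w <- window_candidates(seeds, genome, flank = 336)
  expect_equal(w$start, 664); expect_equal(w$end, 1357)
  seeds2 <- seeds; seeds2$start <- 5; seeds2$end <- 26
  w2 <- window_candidates(seeds2, genome, flank = 336)
  expect_equal(w2$start, 0); expect_equal(w2$end, 362)
  seeds3 <- rbind(seeds, transform(seeds, start = start + 50, end = end + 50))
  w3 <- window_candidates(seeds3, genome, flank = 336)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$n_seeds, 2L)
})

test_that("windows beyond the hard cap are refused", {
  expect_error(scan_inverted_repeats(strrep("A", 10001)), "hard cap")
})
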