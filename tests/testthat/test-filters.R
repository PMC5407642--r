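make_candidate <- function(...) {
  modifyList(list(id = "c1", chrom = "chr1", start = 1000, end = 1150,
                  length = 150, gc = 40, mfe = -50, mfei = 1.1,
                  mature_valid = TRUE, mature_mismatches = 1L), list(...))
}

test_that("cascade boundaries are inclusive and all failures are reported", {
  th <- filter_thresholds()
  expect_false(apply_cascade(make_candidate(gc = 19.9), th)$accepted)
  expect_identical(apply_cascade(make_candidate(gc = 19.9), th)$reasons, "GC_RANGE")
  expect_true(apply_cascade(make_candidate(gc = 20.0, mfei = 0.70), th)$accepted)
  expect_true(apply_cascade(make_candidate(gc = 65.0), th)$accepted)
  expect_false(apply_cascade(make_candidate(gc = 65.1), th)$accepted)
  expect_false(apply_cascade(make_candidate(mfei = 0.699), th)$accepted)
  multi <- apply_cascade(make_candidate(length = 30, gc = 10, mfe = 0,
                                        mfei = 0.1, mature_valid = FALSE,
                                        mature_mismatches = 9L), th)
  expect_identical(multi$reasons,
                   c("LENGTH", "GC_RANGE", "MFE_SIGN", "MFEI_MIN",
                     "MATURE_PLACEMENT", "MATURE_HOMOLOGY"))
  expect_true(all(multi$reasons %in% FILTER_REASONS))
})

test_that("any blocklist overlap rejects, even a single nucleotide", {
  bl <- data.frame(chrom = "chr1", start = 1149, end = 1400)
  d <- apply_cascade(make_candidate(), filter_thresholds(), bl)
  expect_false(d$accepted)
  expect_identical(d$reasons, "BLOCKLIST")
  bl2 <- data.frame(chrom = "chr1", start = 1150, end = 1400)  # abuts, no overlap
  expect_true(apply_cascade(make_candidate(), filter_thresholds(), bl2)$accepted)
})

test_that("missing descriptors are named in the error", {
  c1 <- make_candidate(); c1$mfei <- NULL
  expect_error(apply_cascade(c1), "mfei")
})

test_that("the cascade is monotone in its thresholds", {
  set.seed(61)
  cands <- lapply(1:40, function(i) make_candidate(
    id = paste0("c", i), length = sample(40:400, 1), gc = runif(1, 10, 80),
    mfe = runif(1, -90, 5), mfei = runif(1, 0.2, 2),
    mature_mismatches = sample(0:6, 1)))
  accepted <- function(th) {
    vapply(cands, function(cc) apply_cascade(cc, th)$accepted, logical(1L))
  }
  tight <- filter_thresholds()
  relaxed <- list(
    filter_thresholds(gc_window = c(10, 80)),
    filter_thresholds(mfei_min = 0.3),
    filter_thresholds(length_window = c(40, 400)),
    filter_thresholds(mature_max_mismatches = 6))
  a0 <- accepted(tight)
  for (th in relaxed) expect_true(all(accepted(th) >= a0))
})

test_that("overlap resolution keeps lowest MFE, then longest, then leftmost", {
  df <- data.frame(id = c("a", "b"), chrom = "chr1", start = c(100, 150),
                   end = c(250, 300), strand = "+", mfe = c(-50, -45),
                   stringsAsFactors = FALSE)
  r <- resolve_overlaps(df)
  expect_identical(r$kept$id, "a")
  expect_identical(r$dropped$superseded_by, "a")
  df2 <- data.frame(id = c("short", "long"), chrom = "chr1",
                    start = c(100, 80), end = c(190, 200), strand = "+",
                    mfe = -40, stringsAsFactors = FALSE)
  expect_identical(resolve_overlaps(df2)$kept$id, "long")
  df3 <- data.frame(id = c("x", "y"), chrom = "chr1", start = c(0, 5000),
                    end = c(200, 5200), strand = "+", mfe = -40,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(resolve_overlaps(df3)$kept), 2L)
  # opposite strands never compete
  df4 <- df; df4$strand <- c("+", "-")
  expect_equal(nrow(resolve_overlaps(df4)$kept), 2L)
})

test_that("family assignment picks the closest reference with lexicographic ties", {
  refs <- data.frame(
    mirna_id = c("ath-miR156a", "ath-miR170a", "ath-miR171a"),
    family = c("MIR156", "MIR170", "MIR171"),
    residues = c("TGACAGAAGAGAGTGAGCACA", "TGATTGAGCCGTGCCAATATC",
                 "TGATTGAGCCGCGCCAATATC"), stringsAsFactors = FALSE)
  expect_identical(assign_family("TGACAGAAGAGAGTGAGCACA", refs)$family, "MIR156")
  # 2 mismatches to MIR171, 3 to MIR170
  q <- "TGATTGAGCCGCGCCAATCAC"
  mm171 <- sum(strsplit(q, "")[[1]] != strsplit(refs$residues[3], "")[[1]])
  mm170 <- sum(strsplit(q, "")[[1]] != strsplit(refs$residues[2], "")[[1]])
  expect_equal(c(mm171, mm170), c(2, 3))
  got <- assign_family(q, refs, max_mismatches = 3)
  expect_identical(got$family, "MIR171")
  expect_equal(got$mismatches, 2L)
  # equidistant: lexicographically smallest family wins
  q2 <- "TGATTGAGCCGAGCCAATATC"   # 1 mismatch to each of MIR170/MIR171
  expect_identical(assign_family(q2, refs)$family, "MIR170")
  # nothing within range
  expect_true(is.na(assign_family(strrep("A", 21), refs, 3)$family))
})

test_that("locus names carry per-family letter suffixes in genomic order", {
  nm <- mirdiscover:::.mir_locus_names(
    families = c("MIR156", "MIR156", "MIR172"),
    chrom = c("chr2", "chr1", "chr3"), start = c(50, 10, 5))
  expect_identical(nm, c("ccp-MIR156b", "ccp-MIR156a", "ccp-MIR172"))
})
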