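test_that("fallback fold handles canonical toy cases", {
  f <- fold_rna("GGGAAACCC")
  expect_identical(f$structure, "(((...)))")
  expect_equal(nrow(f$pairs), 3L)
  expect_lt(f$mfe, 0)
  f2 <- fold_rna("AAAAAAA")
  expect_identical(f2$structure, ".......")
  expect_equal(f2$mfe, 0)
  expect_error(fold_rna("ANNNNA"), "N")
})

test_that("fold energy is self-consistent and matches the enumeration oracle", {
  set.seed(51)
  for (k in 1:25) {
    s <- rand_seq(sample(10:30, 1), c("A", "C", "G", "U"))
    f <- fold_rna(s)
    chars <- strsplit(chartr("U", "T", s), "")[[1L]]
    expect_equal(mirdiscover:::.score_structure(chars, f$pairs), f$mfe)
    expect_equal(f$mfe, oracle_fold_mfe(s))
  }
})

test_that("ensemble statistics match exhaustive enumeration", {
  set.seed(52)
  for (k in 1:10) {
    s <- rand_seq(sample(10:22, 1), c("A", "C", "G", "U"))
    o <- oracle_ensemble(s)
    e <- ensemble_stats(s)
    expect_equal(e$mfee, o$mfee, tolerance = 1e-9)
    expect_equal(e$frequency, o$frequency, tolerance = 1e-9)
    expect_equal(e$diversity, o$diversity, tolerance = 1e-9)
    expect_lte(e$mfee, e$mfe + 1e-12)
  }
  # sequence with no pairable bases: single open structure
  e0 <- ensemble_stats("AAAACCCCAAAA")
  expect_equal(e0$frequency, 1)
  expect_equal(e0$diversity, 0)
  expect_equal(e0$mfee, 0)
  expect_error(ensemble_stats(strrep("GC", 16)), "engine required")
})

test_that("AMFE and MFEI follow their defining arithmetic", {
  expect_equal(amfe(-45, 100), -45)
  expect_equal(amfe(-60, 200), -30)
  expect_equal(amfe(0, 77), 0)
  expect_equal(mfei(-45, 50), 0.9)
  expect_equal(mfei(-30, 40), 0.75)
  expect_equal(mfei(-35.2, 40), 0.88)
  expect_error(mfei(-30, 0), "GC")
  # amfe linear in mfe; mfei length-invariant at fixed AMFE and GC
  expect_equal(amfe(-10, 50) + amfe(-20, 50), amfe(-30, 50))
  expect_equal(mfei(amfe(-50, 100), 42), mfei(amfe(-100, 200), 42))
})

test_that("base composition percentages, ratios and revcomp symmetry", {
  b <- base_composition("AUGC")
  expect_equal(unlist(b[c("A", "U", "C", "G")]), c(A = 25, U = 25, C = 25, G = 25))
  expect_equal(b$GC, 50); expect_equal(b$GC_ratio, 1); expect_equal(b$AU_ratio, 1)
  b2 <- base_composition("GGCC")
  expect_equal(b2$GC, 100); expect_equal(b2$AU, 0); expect_true(is.na(b2$AU_ratio))
  b3 <- base_composition("AAAU")
  expect_equal(b3$AU, 100); expect_equal(b3$AU_ratio, 3)
  set.seed(53)
  for (k in 1:10) {
    s <- rand_seq(sample(20:60, 1))
    x <- base_composition(s); y <- base_composition(revcomp(s))
    expect_equal(x$A, y$U); expect_equal(x$G, y$C); expect_equal(x$GC, y$GC)
  }
})

test_that("mature placement assigns arms relative to the dominant loop", {
  stem <- rand_seq(45)
  hp <- paste0(stem, strrep("A", 10), revcomp(stem))   # 100 nt, loop at 46..55
  f <- fold_rna(hp)
  p5 <- place_mature(f, 9, 30)
  expect_true(p5$valid); expect_identical(p5$arm, "5p")
  expect_equal(p5$start, 10); expect_equal(p5$end, 30)
  p3 <- place_mature(f, 69, 90)
  expect_true(p3$valid); expect_identical(p3$arm, "3p")
  bad <- place_mature(f, 39, 60)
  expect_false(bad$valid)
  expect_match(bad$reason, "loop")
})

test_that("multi-branched structures at the mature site are rejected", {
  s1 <- "GGGGG"; s2 <- "GGGGG"
  two <- paste0(s1, "AAAA", revcomp(s1), strrep("A", 30), s2, "AAAA", revcomp(s2))
  f <- fold_rna(two)
  mid <- place_mature(f, 20, 41)   # between the two hairpins
  expect_false(mid$valid)
})

test_that("the vienna engine plugs in and reports coherent values", {
  s <- "GGGGGAAAACCCCCAAAGGGAAACCC"
  f <- fold_rna(s, engine = "vienna")
  expect_identical(f$engine, "vienna")
  expect_lt(f$mfe, 0)
  expect_equal(nchar(f$structure), nchar(s))
  e <- ensemble_stats(s, engine = "vienna")
  expect_lte(e$mfee, e$mfe + 1e-6)
  expect_gt(e$frequency, 0); expect_lte(e$frequency, 1)
  expect_gte(e$diversity, 0)
})
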