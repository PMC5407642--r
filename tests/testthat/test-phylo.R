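test_that("K2P distance matches the closed form and flags saturation", {
  a <- strrep("A", 100)
  expect_equal(k2p_distance(a, a), 0)
  # P = 0.1 (A->G transitions), Q = 0.05 (A->C transversions) over 100 sites
  r1 <- rep("A", 100)
  r2 <- r1; r2[1:10] <- "G"; r2[11:15] <- "C"
  expect_equal(k2p_distance(r1, r2),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)),
               tolerance = 1e-12)
  expect_equal(round(k2p_distance(r1, r2), 5), 0.17018)
  # P = 0.5, Q = 0: saturated
  r3 <- rep("A", 10); r4 <- c(rep("G", 5), rep("A", 5))
  expect_identical(k2p_distance(r3, r4), Inf)
  # gap columns are excluded pairwise; all-gap comparison errors
  expect_equal(k2p_distance(c("A", "-", "C"), c("A", "G", "C")), 0)
  expect_error(k2p_distance(c("-", "-"), c("A", "G")), "zero included sites")
  # cross-check against ape's K80 distance on random alignments
  set.seed(91)
  for (k in 1:5) {
    m1 <- sample(c("A", "C", "G", "T"), 200, TRUE)
    m2 <- ifelse(runif(200) < 0.12, sample(c("A", "C", "G", "T"), 200, TRUE), m1)
    bin <- ape::as.DNAbin(rbind(x = m1, y = m2))
    expect_equal(k2p_distance(m1, m2),
                 as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-9)
  }
})

test_that("protein distances implement p and Poisson models", {
  a <- rep("A", 10)
  expect_equal(protein_distance(a, a, "p-distance"), 0)
  expect_equal(protein_distance(a, a, "poisson"), 0)
  b <- c(rep("A", 9), "C")
  expect_equal(protein_distance(b, a, "poisson"), -log(0.9), tolerance = 1e-12)
  expect_equal(round(protein_distance(b, a, "poisson"), 5), 0.10536)
  allc <- rep("C", 10)
  expect_equal(protein_distance(a, allc, "p-distance"), 1)
  expect_identical(protein_distance(a, allc, "poisson"), Inf)
})

test_that("NJ recovers the 4-taxon additive example with exact branch lengths", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_identical(phylo_splits(tr), "C|D")   # AB|CD split
  cd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cd, D, tolerance = 1e-12)
  # pendant lengths 1,2,3,4 and internal 1 recovered exactly
  expect_setequal(round(tr$edge.length, 10), c(1, 2, 3, 4, 1))
})

test_that("three taxa resolve with the closed form and ties are deterministic", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D3)
  cd <- ape::cophenetic.phylo(tr)[rownames(D3), colnames(D3)]
  expect_equal(cd, D3, tolerance = 1e-12)
  De <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(De) <- 0
  t1 <- ape::write.tree(neighbor_joining(De))
  t2 <- ape::write.tree(neighbor_joining(De))
  expect_identical(t1, t2)
  Dinf <- De; Dinf["a", "c"] <- Dinf["c", "a"] <- Inf
  expect_error(neighbor_joining(Dinf), "non-finite distance")
})

test_that("NJ agrees with the all-topology least-squares oracle on random additive trees", {
  set.seed(92)
  for (n in c(4, 5, 6)) {
    tt <- random_additive_tree(n)
    tr <- neighbor_joining(tt$D)
    best <- oracle_ls_best(tt$D)
    expect_lt(best$sse, 1e-12)
    expect_identical(phylo_splits(tr), best$splits)
    expect_identical(best$splits, tt$splits)
    cd <- ape::cophenetic.phylo(tr)[rownames(tt$D), colnames(tt$D)]
    expect_equal(cd, tt$D, tolerance = 1e-9)
    # independent cross-check: ape's NJ finds the same topology
    expect_identical(phylo_splits(ape::nj(tt$D)), best$splits)
  }
})

test_that("negative branch lengths are clamped with the deficit recorded", {
  D <- matrix(c(0, 2, 2, 2.1,
                2, 0, 0.1, 2,
                2, 0.1, 0, 2,
                2.1, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamp_deficit"), 0)
})

test_that("bootstrap consensus supports behave and collapse below 50%", {
  msa <- withr::with_seed(93, {
    base <- strsplit(rand_seq(60), "")[[1]]
    mut <- function(pos) { x <- base; x[pos] <- chartr("ACGT", "GTAC", x[pos])
                           paste(x, collapse = "") }
    c(t1 = mut(1:2), t2 = mut(2:4), t3 = mut(30:34),
      t4 = mut(c(30:34, 50:52)), t5 = mut(c(30:33, 50:54)))
  })
  bt <- bootstrap_consensus(msa, 200, seed = 42)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 50 & sup <= 100))
  # determinism for a fixed seed
  bt2 <- bootstrap_consensus(msa, 200, seed = 42)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
  # splits and their supports invariant to taxon input order
  bt3 <- bootstrap_consensus(msa[c(4, 2, 5, 1, 3)], 200, seed = 42)
  expect_identical(phylo_splits(bt3), phylo_splits(bt))
  sup3 <- suppressWarnings(as.numeric(bt3$node.label))
  expect_identical(sort(sup3[!is.na(sup3)]), sort(sup))
  # an alignment whose every informative column supports one split: 100%
  msa2 <- c(a = strrep("A", 40), b = strrep("A", 40),
            c = paste0(strrep("G", 10), strrep("A", 30)),
            d = paste0(strrep("G", 10), strrep("A", 30)))
  bt4 <- bootstrap_consensus(msa2, 50, seed = 7)
  expect_identical(phylo_splits(bt4), "c|d")
  expect_equal(suppressWarnings(max(as.numeric(bt4$node.label), na.rm = TRUE)), 100)
  # noisy alignment: retained supports are >= 50 by construction and the
  # 4-taxon consensus can carry at most one internal split
  noise <- withr::with_seed(94, {
    base <- strsplit(rand_seq(40), "")[[1]]
    out <- vapply(1:4, function(i) {
      x <- base
      pos <- sample(40, 8)
      x[pos] <- sample(c("A", "C", "G", "T"), 8, TRUE)
      paste(x, collapse = "")
    }, character(1))
    names(out) <- paste0("n", 1:4)
    out
  })
  bt5 <- bootstrap_consensus(noise, 200, seed = 9)
  sup5 <- suppressWarnings(as.numeric(bt5$node.label))
  sup5 <- sup5[!is.na(sup5)]
  expect_true(all(sup5 >= 50))
  expect_lte(length(sup5), 1L)
})

test_that("trees round-trip through newick", {
  set.seed(95)
  tt <- random_additive_tree(6)
  tr <- neighbor_joining(tt$D)
  tf <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, tf)
  back <- ape::read.tree(tf)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_identical(phylo_splits(back), phylo_splits(tr))
  expect_equal(sort(unname(back$edge.length)), sort(unname(tr$edge.length)),
               tolerance = 1e-6)
})
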