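tpl <- machinery_templates()

test_that("the bundled references carry the canonical catalytic residues", {
  a <- tpl$ago
  expect_identical(substr(a$seq, 760, 760), "D")
  expect_identical(substr(a$seq, 845, 845), "D")
  expect_identical(substr(a$seq, 986, 986), "H")
  expect_identical(substr(a$seq, 798, 798), "H")
  r3 <- tpl$rnase3
  expect_identical(strsplit(substr(r3$seq, 1, 140), "")[[1]][r3$positions],
                   c("E", "D", "D", "E"))
})

test_that("classifying the AGO reference against itself returns DDH/H at the anchor positions", {
  rep <- classify_ago(tpl$ago$seq)
  expect_identical(rep$motif, "DDH/H")
  expect_identical(rep$positions, "760-845-986/798")
  expect_true(rep$evaluable)
})

test_that("anchor mapping follows indels and terminal extensions", {
  ref <- tpl$ago$seq
  # delete 5 residues well before the first anchor
  q <- paste0(substr(ref, 1, 100), substr(ref, 106, nchar(ref)))
  m <- map_reference_positions(q, ref, tpl$ago$anchors)
  expect_equal(unname(m), unname(tpl$ago$anchors) - 5L)
  # appending unrelated sequence at either terminus changes nothing
  set.seed(81)
  pad <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE),
               collapse = "")
  rep <- classify_ago(paste0(pad, ref))
  expect_identical(rep$motif, "DDH/H")
  expect_identical(rep$positions, paste0(760 + 60, "-", 845 + 60, "-", 986 + 60,
                                         "/", 798 + 60))
  # a query truncated before the anchors is not evaluable
  short <- substr(ref, 1, 400)
  rep2 <- classify_ago(short)
  expect_false(rep2$evaluable)
  expect_match(rep2$motif, "\\?")
})

test_that("AGO motif variants observed in planted proteins are reproduced", {
  variants <- list(
    list(rules = character(), motif = "DDH/H"),
    list(rules = "H986->D", motif = "DDD/H"),
    list(rules = "H798->S", motif = "DDH/S"),
    list(rules = "H798->P", motif = "DDH/P"),
    list(rules = "H798->Q", motif = "DDH/Q"),
    list(rules = c("D760->E", "D845->N", "H986->R", "H798->R"), motif = "ENR/R"))
  for (v in variants) {
    sp <- synth_proteins(seed = 82, n_ago = 1, n_dcl = 0, n_rdr = 0,
                         corruptions = list(synAGO1 = v$rules))
    got <- classify_ago(sp$proteins[["synAGO1"]])
    expect_identical(got$motif, v$motif)
  }
})

test_that("DCL RNase III domains yield per-domain EDDE motifs", {
  sp <- synth_proteins(seed = 83, n_ago = 0, n_dcl = 2, n_rdr = 0,
                       corruptions = list(synDCL2 = "RIBOc1:1->Q"))
  d1 <- classify_dcl(sp$proteins[["synDCL1"]],
                     sp$domains[sp$domains$protein_id == "synDCL1", ])
  expect_identical(d1$motif, "EDDE/EDDE")
  expect_false(d1$partial)
  d2 <- classify_dcl(sp$proteins[["synDCL2"]],
                     sp$domains[sp$domains$protein_id == "synDCL2", ])
  expect_identical(d2$motif, "QDDE/EDDE")
  # single RIBOc: partial; none: not evaluable
  dom1 <- sp$domains[sp$domains$protein_id == "synDCL1", ]
  one <- dom1[dom1$domain_name == "RIBOc", ][1, , drop = FALSE]
  dpart <- classify_dcl(sp$proteins[["synDCL1"]], one)
  expect_identical(dpart$motif, "EDDE")
  expect_true(dpart$partial)
  dnone <- classify_dcl(sp$proteins[["synDCL1"]],
                        dom1[dom1$domain_name == "PAZ", ])
  expect_false(dnone$evaluable)
})

test_that("RDR motif scan reproduces the clade dichotomy and agrees with substring search", {
  sp <- synth_proteins(seed = 84, n_ago = 0, n_dcl = 0, n_rdr = 4,
                       corruptions = list(synRDR2 = "DLDGD->DFDGD",
                                          synRDR3 = "CSGS->ASGS",
                                          synRDR4 = "DLDGD->DMDGD"))
  r1 <- classify_rdr(sp$proteins[["synRDR1"]])
  expect_identical(r1$clade, "alpha"); expect_identical(r1$subseq, "CSGS")
  r2 <- classify_rdr(sp$proteins[["synRDR2"]])
  expect_identical(r2$clade, "gamma"); expect_identical(r2$motif, "DFDGD")
  r3 <- classify_rdr(sp$proteins[["synRDR3"]])
  expect_identical(r3$clade, "alpha"); expect_identical(r3$subseq, "ASGS")
  r4 <- classify_rdr(sp$proteins[["synRDR4"]])
  expect_false(r4$evaluable)
  # agreement with a brute-force substring scan
  for (id in names(sp$proteins)) {
    q <- sp$proteins[[id]]
    brute <- NA_integer_
    for (p in seq_len(nchar(q) - 4L)) {
      w <- substr(q, p, p + 4L)
      if (substr(w, 1, 1) == "D" && substr(w, 2, 2) %in% c("L", "F") &&
          substr(w, 3, 3) == "D" && substr(w, 4, 4) == "G" &&
          substr(w, 5, 5) == "D") { brute <- p; break }
    }
    got <- classify_rdr(q)
    if (is.na(brute)) expect_false(got$evaluable)
    else expect_equal(got$mapped, brute)
  }
})

test_that("domain architecture completeness follows the family templates", {
  dcl_full <- data.frame(
    protein_id = "D1",
    domain_name = c("DExD", "Helicase-C", "DUF283", "PAZ", "RIBOc", "RIBOc",
                    "DSRM", "DSRM"),
    start = c(114, 503, 693, 1029, 1201, 1423, 1582, 1674),
    end = c(266, 619, 784, 1164, 1387, 1579, 1643, 1742), stringsAsFactors = FALSE)
  a <- classify_architecture("D1", dcl_full, "DCL")
  expect_true(a$complete); expect_true(a$order_ok)
  # a truncated DCL2-like protein lacking the N-terminal domains and PAZ
  dcl_trunc <- dcl_full[dcl_full$domain_name == "RIBOc", ]
  b <- classify_architecture("D1", dcl_trunc, "DCL")
  expect_false(b$complete)
  expect_setequal(names(b$missing), c("DExD", "Helicase-C", "DUF283", "PAZ"))
  ago_no_mid <- data.frame(protein_id = "A1",
                           domain_name = c("ArgoN", "PAZ", "Piwi"),
                           start = c(253, 458, 758), end = c(393, 581, 1052),
                           stringsAsFactors = FALSE)
  expect_true(classify_architecture("A1", ago_no_mid, "AGO")$complete)
  expect_error(classify_architecture("A1", ago_no_mid, "XYZ"), "unknown family")
})

test_that("whole-proteome classification matches the generator's expected reports", {
  sp <- synth_proteins(seed = 85, n_ago = 2, n_dcl = 1, n_rdr = 2,
                       corruptions = list(synAGO2 = "H798->S",
                                          synRDR2 = "DLDGD->DFDGD"))
  got <- run_machinery(sp$proteins, sp$domains, sp$families)
  expect_identical(got$protein_id, sp$expected$protein_id)
  expect_identical(got$motif, sp$expected$motif)
  expect_identical(got$clade, sp$expected$clade)
  expect_identical(got$subseq, sp$expected$subseq)
  expect_true(all(got$evaluable))
  # unknown corruption rules error
  expect_error(synth_proteins(seed = 1, corruptions = list(synAGO1 = "Z9->Q")),
               "unknown corruption")
  # AGO-only proteome yields AGO rows only
  ago_only <- synth_proteins(seed = 86, n_ago = 2, n_dcl = 0, n_rdr = 0)
  r <- run_machinery(ago_only$proteins, ago_only$domains, ago_only$families)
  expect_true(all(r$family == "AGO"))
})
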