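Package: mirdiscover
Title: Homology-Guided Plant miRNA Discovery and RNA-Silencing Machinery Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable re-implementation of a genome-wide small-RNA pathway
    analysis for plants: homology-guided discovery of miRNA precursors
    (mature-seeded window scan, inverted-repeat detection with einverted-style
    scoring, hairpin folding and MFE/AMFE/MFEI thermodynamic profiling, a
    filter cascade with per-candidate rejection reasons), genomic annotation
    of MIR loci (genic/intergenic calls, 10-kb clustering, per-chromosome
    summaries), catalytic-motif classification of AGO/DCL/RDR silencing
    proteins (DDH/H slicer triad, EDDE RNase III residues, DxDGD polymerase
    motif), psRNATarget-style miRNA target scoring, and distance-based
    phylogenetics (Kimura two-parameter and protein distances,
    neighbor-joining, bootstrap majority-rule consensus). A synthetic-data
    generator with known ground truth exercises every stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
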