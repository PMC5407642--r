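---
title: "Methods: homology-guided miRNA discovery and machinery annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-guided miRNA discovery and machinery annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdiscover)
```

# The analysis

Plant MIR surveys proceed from one observation: mature miRNAs are strongly
conserved across species while their precursors diverge. A new genome can
therefore be screened by (1) locating near-exact copies of known matures,
(2) asking whether the surrounding sequence folds back into a hairpin, and
(3) filtering the hairpins on the thermodynamic and compositional signatures
that separate genuine pre-miRNAs from repeats, inverted duplications and
other ncRNAs. `mirdiscover` implements that pipeline end to end, together
with the two companion analyses such surveys report: catalytic-residue
classification of the silencing machinery (DCL, AGO, RDR) and
miRNA-target prediction, plus distance-based phylogenetics for both
precursors and proteins.

# Discovery

## Homology seeding

Seeding is an ungapped Hamming scan of the genome (both strands) against the
reference matures, with a default tolerance of 3 mismatches. Mature miRNAs
are 19–25 nt; at that length a gapped local-alignment seed adds sensitivity
only for indel variants, which are rare among conserved matures, while an
ungapped scan is exactly checkable against a brute-force oracle and fully
deterministic. The tolerance is configurable (`max_seed_mismatches`).

Each seed is expanded by one maximum repeat extent (336 nt) on each side,
clipped at chromosome ends, and overlapping windows are merged with seed
provenance retained.

## Inverted-repeat detection

Windows are scanned by local alignment of the sequence against its own
reverse complement with the einverted-convention scoring — match +3,
mismatch −4, gap 12 per gap position (linear, not affine) — a reporting
threshold of 25 and a maximum repeat extent of 336 nt; the minimum loop is
3 nt. The recurrence is filled per row with a running-maximum transform, so
the scan is quadratic with vectorised inner operations. Reported repeats are
mutually non-overlapping, sorted by score, then leftmost start, then
shortest extent, and each repeat's score is reproducible from its traceback
(arms, loop, percent identity, gap count). Windows longer than a hard cap
(default 10 kb) are refused; callers are expected to pre-window, which the
pipeline always does.

A candidate precursor is the outer span of an inverted repeat that contains
at least one seed; the seed with the fewest mismatches (ties: plus strand,
then leftmost) fixes the orientation and the mature interval. For a perfect
fold-back both orientations are legitimate reads of the same locus — the
opposite arm carries the exact reverse complement of the mature — so truth
evaluation on synthetic data matches loci strand-agnostically.

## Folding and descriptors

The folding engine is pluggable. The built-in fallback engine maximises
weighted base pairs with a stacking bonus: pair energies GC = −3, AU = −2,
G·U = −1, an extra −1 for each directly stacked pair, and a minimum hairpin
loop of 3 nt. Energies are integers, so optima and traceback ties are exact;
the traceback deterministically prefers pairing the 5′-most base with its
outermost admissible partner. These are not kilocalories: the fallback
engine ranks hairpins correctly and is fully reproducible with no external
dependency, but its MFE/AMFE/MFEI values sit on an inflated scale (roughly
2–3× the thermodynamic one for perfect stems). The `vienna` engine shells
out to RNAfold when the binary is on the PATH and yields kcal/mol values at
37 °C; outputs record the engine identity so descriptor tables are never
mixed silently.

Descriptors follow the standard definitions: `AMFE = (MFE/length)·100` and
`MFEI = |AMFE| / GC%`. The MFEI is reported as a positive magnitude; plant
pre-miRNAs typically fall in 0.7–1.7 under thermodynamic energies, which is
what makes the index discriminative. (A literal reading of the formula as
sometimes printed, AMFE × 100 / GC%, is dimensionally inconsistent with that
range; the convention here reproduces it.)

Ensemble quantities use `MFEE = −RT ln Z`,
`Frequency = exp((MFEE − MFE)/RT)` and ensemble diversity defined as the
expected base-pair distance between two structures drawn independently from
the Boltzmann ensemble, `2 Σ p(1−p)` over pair probabilities, with
RT = 0.61633 kcal/mol. The fallback engine computes them by exact exhaustive
summation over the complete structure ensemble (an inside partition-function
recursion, with pair probabilities obtained by banning each admissible pair
in turn); this is limited by contract to sequences of at most 30 nt, beyond
which the engine refuses with "engine required" — full-length precursors
need the thermodynamic engine. Tests verify the summation against explicit
structure-by-structure enumeration.

The mature arm is assigned relative to the dominant terminal loop (the
hairpin loop closing the deepest stem): 5p if the mature lies entirely left
of it, 3p if entirely right. Matures overlapping the loop, or sitting in
multi-branched context (another hairpin loop between them and the dominant
one), are rejected rather than heuristically resolved.

## Filter cascade

Filters run in a fixed order — length, GC window, MFE < 0, MFEI minimum,
mature placement, mature homology, blocklist — and report *all* failures,
not just the first, as a closed reason vocabulary. Defaults:

| filter | default | rationale |
|---|---|---|
| precursor length | [60, 338] nt inclusive | brackets the observed plant range (68–338) with slack at the low end |
| GC content | [20, 65] % inclusive | the survey's stated compositional window |
| MFE | < 0 | surveys list MFE as a filter without a cutoff; only the sign is required |
| MFEI | ≥ 0.7 | accepted plant precursors span 0.7–1.7; the low edge is the natural threshold, configurable |
| mature homology | ≤ 3 mismatches | the seeding tolerance, restated against the full reference set |
| blocklist | any overlap rejects | repeat/ncRNA masking is consumed as intervals, not recomputed |

All boundaries are inclusive and covered by paired just-inside/just-outside
tests. Overlapping accepted candidates on the same strand reduce to one
precursor per locus: lowest MFE, then longest, then leftmost, with
provenance links from the dropped candidates. Loci are named
`ccp-MIR<family>` with per-family letter suffixes in genomic order.

## Genomic context

A precursor is genic iff it overlaps any gene interval by ≥ 1 nt,
strand-agnostic, using gene-level features only — the published tables
report a binary genic/intergenic label, so exon structure is not consulted.
Clusters chain consecutive precursors per chromosome whose end-to-start gap
is at most 10,000 nt, inclusive; the anchor points (interval boundaries, not
midpoints) and the inclusive boundary are declared conventions, tested at
exactly 10,000. Singletons are not clusters; a cluster containing both
strands is flagged antiparallel. Internally all coordinates are 0-based
half-open; every user-facing report is 1-based inclusive.

# Machinery classification

Catalytic residues are located by mapping anchor positions from a reference
through a global pairwise alignment (BLOSUM62, gap open 10, extend 0.5 —
declared defaults, since residue-mapping parameters are rarely printed).
The package cannot bundle curated reference proteins, so it ships
deterministic **synthetic** anchor scaffolds with the canonical residues
planted at the literature coordinates: an AGO-like scaffold with D760, D845,
H986 and the auxiliary H798, and an RNase III-like scaffold with the E-D-D-E
residues. Any user-supplied reference with annotated anchor positions can be
swapped in (`classify_ago(query, reference, anchors)`); results on divergent
queries are as good as the alignment, and anchors falling in gaps are
reported as unevaluable rather than guessed.

RDR classification is a deterministic pattern scan — `D[LF]DGD` for the
catalytic motif (L: α clade; F: γ clade) and `[CA]SG[SG]` in the 30 residues
upstream — replacing stochastic motif discovery with an exactly checkable
rule; when several matches occur, the leftmost inside an annotated RdRP
domain wins. Architecture completeness compares observed domain multisets
against family templates and reports missing/extra domains and ordered-
position sanity.

# Target prediction

Scoring follows the published psRNATarget schema: per-position penalties of
1 (mismatch), 0.5 (G:U) and 2 (gap), doubled at miRNA positions 2–13, summed
into an expectation (lower is better) with an inclusive cutoff of 2.0. At
most one gap per duplex is allowed by default, its position enumerated
exhaustively. The inhibition call is "translation" iff a mismatched or
unpaired position falls wholly within miRNA positions 9–11, else "cleavage";
G:U wobbles count as paired. Overlapping candidate sites resolve
leftmost-best (lowest expectation, then leftmost). The complementarity
window (hspsize 20) is recorded; matures shorter than it are scored over
their full length. Target-site accessibility (UPE) is carried through the
data model as an optional externally supplied field and never computed here.

# Phylogenetics

Distances from pre-aligned sequences: Kimura two-parameter for nucleotides,
`d = −½ ln[(1−2P−Q)√(1−2Q)]` with transition/transversion proportions P and
Q, flagged infinite at saturation; p-distance or Poisson (`−ln(1−p)`) for
proteins. The Poisson correction stands in for maximum-likelihood JTT
distances: at the divergences involved the NJ topology is robust to this
substitution, and output metadata records the model actually used. Gap
handling defaults to complete deletion (every column containing a gap
removed before any comparison), matching the convention stated in published
tree legends; pairwise deletion is available.

Neighbor-joining is the standard agglomeration with two declared
conventions: ties in the Q criterion break to the lowest index pair, and
negative branch lengths are clamped to zero with the total deficit recorded
as an attribute. On additive matrices the algorithm recovers the generating
topology and branch lengths exactly, which the tests verify against an
all-topology least-squares oracle.

Bootstrap consensus resamples alignment columns with replacement, builds an
NJ tree per replicate, and returns the majority-rule consensus: bipartitions
reproduced in fewer than 50 % of replicates are collapsed, supports are
integer percentages, and consensus branch lengths are means over the
replicates containing each branch. Taxa are put in canonical (sorted) order
before resampling so supports cannot depend on input order even when NJ
ties occur. Support values attach to bipartitions of the leaf set and are
therefore rooting-invariant.

# The synthetic study

`synth_config()` defaults define the study conditions used throughout the
tests and the acceptance script: 12 chromosomes (including `chr0`, the
unplaced-scaffold pseudochromosome, treated as ordinary) of 20 kb, 20
planted fold-back precursors with arms of 50–110 nt and loops of 8–30 nt
(precursors ≈ 110–250 nt, inside the 60–338 filter window), mismatch-free
opposite arms, background GC 0.38, mature lengths 19–25 nt with a 21-nt
mode allocated *exactly* by largest-remainder apportionment, a 60 %
probability of a 5′ uracil, one fifth of loci inside genes (held exactly),
five decoy hairpins whose intervals form the blocklist, and one reference
mature per planted family within a 1-mismatch budget. These sizes keep a
full discovery run around 15 s on one CPU while exercising every stage;
they are the package's chosen desk-scale emulation of a genome-wide survey,
not estimates of any real genome's parameters.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: background composition is i.i.d. (no repeats,
no isochores, no higher-order structure beyond the planted decoys), planted
hairpins are perfect duplexes rather than bulged natural precursors, and
expression evidence is out of scope. Consequences worth knowing: perfect
hairpins are orientation-symmetric, so detected strand is ambiguous by
construction; and their fold energies are stronger than natural precursors,
so descriptor means computed on synthetic data (for example a mean MFEI
above 2 under thermodynamic energies) sit above the 0.7–1.7 range typical
of real plant precursors. With mismatch-free plants and decoys blocklisted,
discovery precision and recall against the planted truth are exactly 1.0,
and that is the designed behaviour, not a measured discovery rate on real
genomes.

# Numerical choices and degenerate inputs

- Integer energies in the fallback engine make every optimum and tie exact;
  no floating-point tolerance enters folding or the inverted-repeat DP.
- All randomness flows through explicit seeds (`synth_config(seed)`,
  `bootstrap_consensus(..., seed)`); no stage reads ambient RNG state, and
  a private RNG scope restores the caller's `.Random.seed`.
- Empty inputs (no references, no candidates, empty precursor sets) return
  empty, well-typed tables rather than errors; malformed records error with
  the offending record id or line number.
- Sequences with more than 10 % N are refused by the folding engine;
  composition percentages are computed over non-N residues; ratios with a
  zero denominator are `NA`.
- `k2p_distance` errors when no sites remain after gap exclusion and flags
  saturated pairs `Inf`; `neighbor_joining` refuses non-finite distances,
  naming the offending pair.

# Limitations

- The fallback engine's energy scale is not thermodynamic; use the `vienna`
  engine for kcal/mol descriptors and ensemble statistics of full-length
  precursors.
- Homology seeding cannot find miRNAs without a close reference mature
  (no de-novo discovery), and indel-variant matures are invisible to the
  ungapped scan.
- Machinery anchors are synthetic scaffolds; absolute residue positions in
  divergent real proteins may shift by a few residues relative to published
  tables, exactly as alignment choice shifts them between studies.
- Consensus branch lengths are replicate means, a display convention; for
  publication-grade branch lengths compute them on the original alignment.
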