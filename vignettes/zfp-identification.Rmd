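---
title: "Identifying and classifying C2H2 zinc finger proteins with zfpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and classifying C2H2 zinc finger proteins with zfpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

C2H2 zinc finger proteins (ZFPs) form one of the largest transcription-factor
families in plants. The finger itself is a short motif,
X2-Cys-X2,4-Cys-X12-His-X3,4,5-His, in which the two cysteines and two
histidines coordinate a zinc ion; everything outside the finger varies
enormously between family members. A genome-wide survey of the family
therefore reduces to a chain of well-defined operations: scan every annotated
protein for the motif, weed out false positives with an external profile
scan, classify each finger by its conserved core, aggregate fingers and EAR
repression motifs into per-protein architectures, relate family members to
their positions in the gene order (local duplication being the main engine of
family expansion in *Medicago*-like genomes), and tier the genes by
transcript abundance. `zfpkit` implements that chain as composable functions
plus a pipeline driver, and ships a synthetic-data generator that plants
every feature with known labels so the whole chain is testable end to end
without downloading a genome.

## Scanning model

Two fixed-geometry regular expressions are used, `.{2}C.{2}C.{12}H.{3,5}H`
and `.{2}C.{4}C.{12}H.{3,5}H`. In `published` mode each pattern is applied
independently with the default semantics of a scripting-language regex
engine: leftmost, non-overlapping matches with a greedy inter-His gap (the
longest of 3-5 residues that matches at an anchor wins). The two result sets
are then merged; where a C-X2-C call and a C-X4-C call overlap, the C-X2-C
call is kept, because C-X2-C is the canonical geometry and keeping both
would double-count one physical finger. `exhaustive` mode enumerates every
window satisfying either pattern, overlaps included; it exists purely as an
oracle superset — the test suite checks `published ⊆ exhaustive` and checks
`exhaustive` against an independent brute-force enumerator.

Two consequences of the pattern are worth stating. The shortest matchable
window is 2+1+2+1+12+1+3+1 = 23 residues. And the leading `.{2}` means a
cysteine at position 0 or 1 of a protein can never anchor a finger; this is
faithful to the published pattern even though it is biologically arbitrary.

Coordinates are 0-based half-open internally; exported feature files are
1-based inclusive (GFF convention).

EAR repression motifs are scanned with the two canonical classes, `LxLxL`
and `DLNxxP`, leftmost non-overlapping per pattern. The pattern set is
configurable in the rules file, since EAR is used loosely in the literature;
an EAR-like site can legitimately sit *inside* a finger (the TRM1 case),
which the architecture layer reports as a flagged overlap rather than an
arrangement class.

## Classification model

Fingers are typed with precedence Q → QM → IDD → Z → C:

* **Q**: the six residues ending at the first histidine (`core6`) are
  exactly `QALGGH`. Subgroups come from the three residues between the two
  histidines — Q1 `QNA`, Q2 `(K/R)AS`, Q3 `MR(R/K)`, Q4 `MN(I/V)`,
  Q5 `KR(C/S)` — and only when the inter-His gap is exactly three residues,
  because the consensus is defined over three positions; Q fingers with a
  4-5 residue gap, or a non-consensus triplet, fall to Q6.
* **QM** ("Q-modified"): Hamming distance 1-2 from `QALGG` on the five
  pre-His core positions (the sixth position is structurally His). The
  subgroup label is the mismatch signature (e.g. `P1:R` for `RALGGH`); an
  override table can be loaded from the rules file when an external subgroup
  scheme should be matched exactly.
* **IDD**: the highly conserved finger of INDETERMINATE-DOMAIN proteins —
  a 23-residue finger starting with phenylalanine in which at least 16 of 23
  positions agree with a per-position reference profile
  (`build_idd_profile()`). The packaged profile is built from a clearly
  labelled **synthetic** reference set
  (`inst/extdata/idd_reference_synthetic.fasta`) that carries the structural
  hallmarks of IDD fingers (leading F, ≥16 invariant positions); users with
  a curated IDD set should rebuild the profile from it. Fingers longer than
  23 residues are never IDD under this rule, since the profile is an
  ungapped 23-column alignment.
* **Z**: conserved cores outside the above. The primary path matches a
  core-signature table from the rules file; without one, the remaining
  fingers are clustered by deterministic single-linkage on pairwise identity
  of the full motif string (default threshold 0.60, minimum cluster size 2),
  and clusters become Z subgroups labelled in order of their smallest member
  protein id. Single linkage was chosen because it is parameter-light and
  fully deterministic; it is *not* a phylogenetic statement.
* **C**: the residual class, no conserved core.

Typing is a partition: each finger receives exactly one type, and subgroup
counts within a type sum to the type count — both are enforced by tests.

## Architecture, arrays, duplications

Within a protein, the *linker* between consecutive fingers is the number of
residues strictly between the matched spans. A tandem array is a maximal run
of fingers in which every linker is shorter than 11 residues
(`--tandem-max-linker`); singleton runs are not arrays. The threshold is the
operational rule stated with the method this package reimplements; note the
same literature also describes array spacers "from zero to 11", an
off-by-one its own Methods section resolves in favour of the strict `< 11`.
Array calling is monotone in the threshold (tested).

EAR arrangement is decided on feature midpoints for single-finger proteins:
one EAR downstream → `C2H2_then_EAR` (the PALM1/RSD layout), one upstream →
`EAR_then_C2H2` (the JAG layout), two EARs with the finger between them →
`C2H2_between_EARs`, two on one side → `EARs_flanking_other`, three or more
→ `mixed`. Multi-finger proteins only get a directional label when every EAR
is strictly on one side of every finger.

Local gene duplication is called on gene-order ranks: per chromosome, family
genes whose consecutive members are at most 100 gene models apart are
chained transitively, and maximal chains of two or more are clusters. The
window applies pairwise-consecutively (so a cluster can span more than 100
ranks end to end), matching the convention of rank-window tandem-duplication
callers; the window is configurable. WGD pairs are *ingested*, never
detected — synteny scanning is out of scope — and each ingested pair is
checked for motif-architecture concordance (equal finger type strings).

## Physicochemical profile

Molecular weight is the sum of average residue masses plus one water
(75.07 Da for `G`, additive under concatenation minus one water). The
isoelectric point is found by bisection on the Henderson–Hasselbalch net
charge over pH 0–14 (|charge| < 1e-4 or 100 iterations), using the EMBOSS
pKa table (N-term 8.6, C-term 3.6; K 10.8, R 12.5, H 6.5, D 3.9, E 4.1,
C 8.5, Y 10.1); the table name is recorded on the result. Different pKa sets
shift pI by up to ~0.3 pH units; self-consistency (zero charge at the
returned pI) and permutation invariance are the tested contracts.

## Expression tiers and induction

Abundances are log2-transformed with a pseudocount of 1. Genes are ranked by
mean log2 abundance and split into near-equal tertiles (low/medium/high;
ties broken by gene id, extra genes to lower tiers, cut values reported),
because the heatmap grouping this mirrors states no thresholds — tertiles
are the transparent default. "Obvious induction" in a target tissue set is
operationalized as target mean ≥ 2× the non-target mean; the score is
scale-invariant and the fold is configurable.

## The synthetic-data generator

`synthetic_spec()` defaults to the study-scale conditions this package is
tested against: 272 scan candidates (55 marked drop by the confirmation
list) leaving 217 proteins with 328 fingers, plus an appended nine-finger
TFIIIA-like record (218/337); type counts 93/57/19/41/127 for Q/QM/IDD/Z/C
with Q1..Q6 = 28/22/12/10/10/11 and eight Z subgroups of 15/7/5/4/3/3/2/2;
finger-count classes 151/38/16/9/1/2/1; EAR classes 74/60/17 among
single-finger proteins; 15 tandem-array proteins (including a TRM1-like
five-finger protein whose fifth finger embeds an `LKLHL` site, and the
TFIIIA-like record with its 2-4 and 5-9 arrays); 46 local-duplication
clusters over eight chromosomes with 59 of 218 genes on chromosome 1; and
119 genes with expression probesets of which 14 are nodule-induced, the
strongest (fold 64) being an RSD-like single-finger EAR protein. The
TRM1-like array linkers are kept below the 11-residue threshold so that the
operational array rule reproduces the 15 tandem-array proteins.

Flanks and linkers are drawn from an alphabet excluding C and H, so planted
fingers are provably the only scanner matches, and additionally excluding L,
so planted EAR sites are the only `LxLxL`/`DLNxxP` matches. Tier means are
separated by 4 log2 units with noise of 0.2 log2 units, and planted
induction folds are ≥ 8 against a fold-2 flag threshold, chosen once so that
recovery is unambiguous at any seed. One seed drives everything;
regeneration is byte-identical.

What the generator does *not* emulate: realistic amino-acid composition,
homology between family members outside the planted motifs, annotation
errors, probe cross-hybridization, or genome assembly artifacts. Passing
tests on clean synthetic data therefore demonstrate the correctness of the
operations, not the field behaviour of the scanner on a real, dirty
proteome — on real data the confirmation step exists precisely because the
pattern alone over-calls.

## Problem sizes and determinism

The default test and acceptance runs use the study-scale bundle
(~590 protein records, ~16,000 gene models, 119 × 10 expression values),
which completes in seconds on one CPU; the planted-recovery property test
uses a 500-protein proteome. All pipeline outputs are written with stable
column and row order, and the run manifest carries versions, thresholds,
seed and counts, so reruns on identical inputs are byte-identical.

## Known limitations

* The cross-annotation merge used when two genome versions are combined into
  one family list is not modelled; each proteome is treated independently,
  with an id-pair mapping file as the hook for cross-version merging.
* PROSITE/PFAM confirmation, BLAST homology naming, HMM profiles,
  phylogenetics and synteny detection are out of scope; their results enter
  only as ingestible tables.
* The packaged IDD reference set is synthetic; exact agreement with an
  externally curated IDD subgroup scheme requires rebuilding the profile
  from that scheme's sequences.
* Q subgrouping ignores fingers with non-3-residue inter-His gaps by design;
  a consensus over variable-length gaps would need an alignment model the
  source rule does not define.
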