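---
title: "Signature-motif discrimination of plant TDC and TYDC: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-motif discrimination of plant TDC and TYDC: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Plant aromatic L-amino-acid decarboxylases split into two functional
groups that annotation pipelines often confuse: tryptophan decarboxylases
(TDC, EC 4.1.1.28), which commit tryptophan to the indole-alkylamine
("tryptamine") branch, and tyrosine/DOPA decarboxylases (TYDC), which act
on phenolic substrates. The two groups share high overall sequence
similarity — database entries are frequently labeled only "aromatic
L-amino-acid decarboxylase" — yet they differ at a handful of short,
strongly conserved sequence motifs near the substrate-binding and
PLP-binding regions. `tdcsig` operationalizes that observation three ways:

1. **Classification.** Given the four signature pairs (packaged as a
   fixture; each pair is a TDC variant and a TYDC variant of the same
   conserved block), a query protein is scanned for both variants of each
   pair and votes are tallied.
2. **Discovery.** Given a class-labeled multiple alignment, the package
   recomputes such signature pairs from scratch: per-column, per-class
   minimal covering residue sets, disjointness between classes, and
   extraction of maximal conserved runs.
3. **Corroboration.** A progressive aligner, Dayhoff-corrected distances,
   neighbor joining and column bootstrap reproduce the expected two-cluster
   (TDC vs TYDC) topology on families with planted signal.

A fourth, independent component handles the mass-spectrometric side of
identifying the *products* of TDC activity: the MRM transition arithmetic
for tryptamine and its N-methyl derivatives, with indole-ring d5 labeling.

# The signature model

A degenerate motif is an ordered list of allowed-residue sets, written in
the bracketed dialect `T[H/N]W[L/M]SP`. A *signature pair* couples the TDC
and TYDC variants of one conserved block; its *diagnostic offsets* are the
positions where the two allowed sets are disjoint, so a single residue
there is class-deciding. The packaged set has four pairs (anchors given in
the reference numbering of each family):

| TDC | TYDC | diagnostic offsets |
|---|---|---|
| `T[H/N]W[L/M]SP` (92) | `THWQSP` (137) | 4 |
| `FPATVSSAAF` (103) | `[F/Y][P/A]S[S/N][G/S/T]S[I/V/T]AGF` (148) | 3, 4, 5, 7, 9 |
| `[H/Q][G/N]TTSE[A/S]ILCT` (167) | `QGT[T/A/S][C/S]EA[V/I]L[C/V][T/V]` (217) | none |
| `SPHKW` (318) | `NAHKW` (369) | 1, 2 |

Diagnostic offsets are always *recomputed* from the patterns
(`diagnostic_positions()`); the fixture's `diagnostic_hint` field only
records which residues the curated table highlighted, and the test suite
asserts the two agree. Note the third pair has **no** disjoint column —
every position's alternatives overlap — which shapes the classification
default below.

Matching is ungapped (the blocks are short and contiguous in real
alignments), `X` never satisfies a set, and anchor positions are metadata
only, never used for matching.

# Classification rule

For each pair, both variants are scanned over the query
(`scan_motif()`). With `strict_diagnostic = TRUE` (default) a window only
counts if every diagnostic offset matches exactly; the remaining offsets
may mismatch at up to `max_mismatch` positions (default 1). The variant
with the strictly smaller best mismatch count wins the pair's vote; ties
or double misses abstain. A label needs `min_votes` (default 3) and a
lead of `margin` (default 1); zero total votes is `UNCLASSIFIED`,
anything else `AMBIGUOUS`.

`min_votes = 3` of 4 is deliberate: because pair 3 carries no diagnostic
offset, both of its variants can match the same sequence equally well
(abstaining), so demanding 4/4 would be fragile, while 3/4 still requires
unanimous support from the three genuinely discriminative pairs. The
per-pair defaults are this package's own calibration — the qualitative
rule they formalize ("selected based on amino-acid composition in the four
characterizing motifs") does not fix a tolerance — and they are exposed in
`classification_config()`.

Two properties are enforced by tests: swapping every pair's two motifs
swaps TDC/TYDC labels on any input, and the total number of votes is
monotone in `max_mismatch`.

# Discovery from labeled alignments

`find_diagnostic_columns()` formalizes "conserved in all members of a
class with minor differences": a column is conserved within a class when
its gap fraction is at most `max_gap_fraction` (default 0.1) and the
smallest residue set covering at least `1 - coverage` of the class's
non-gap members (default `coverage = 0`: every member) has at most
`max_set_size` residues (default 3, the largest alternative count in the
packaged table). A column is diagnostic when both classes are conserved
with disjoint sets. Minimal covering sets, rather than entropy, define
conservation because they directly yield the `[X/Y]` output dialect.

`extract_motif_pairs()` reports maximal runs of columns conserved in both
classes, bridging at most `merge_gap` (default 1) non-conserved columns,
keeping runs of at least `min_length` (default 4) columns that contain at
least one diagnostic column. All qualifying pairs are reported; selecting
among them is left to the user. Reference positions are mapped through
`column_to_reference_position()` (non-gap prefix count in a chosen
reference row).

# Synthetic families and what they do (not) show

`generate_family()` emits two classes of equal-length sequences built on
**one shared random backbone**: each record gets its class's four motif
variants written at fixed anchors (defaults: the packaged reference
anchors in a 500-residue chain, all eight windows mutually disjoint), with
every degenerate motif position drawn uniformly from its allowed set, and
independent substitution noise at rate `mu` (default 0.05, uniform over
the 19 alternative residues) outside the class's motif windows. Motif
windows themselves are noise-free: the class signal is exact, mirroring
the premise that the signatures are conserved in all members; their only
variability is the allowed-set sampling, which is already the
"in-motif noise restricted to allowed sets" regime.

The ground truth records the planted diagnostic columns from the
*class-ancestor construction*: per column, a class's residue set is the
motif's allowed set inside its windows and the backbone singleton
elsewhere, and a column is planted-diagnostic when the two classes' sets
are disjoint. Because the backbone is shared, only motif columns can
qualify, and a motif column qualifies exactly when the other class's
backbone residue escapes the motif's allowed set — so the planted count
varies slightly with the backbone draw (typically ~55-61 of the 64 motif
columns).

Design consequences worth knowing:

- With a shared backbone and `mu = 0`, *every* column is conserved in
  both classes, so conserved-run extraction returns one run spanning the
  alignment; distinct blocks only delineate themselves when flanking
  columns are non-conserved (noise, or per-row random backbones as used in
  the block-recovery tests). Diagnostic-column recovery is unaffected.
- The generator plants no indels, so the identity alignment of the emitted
  sequences is the natural coordinate system; the discovery and tree
  properties are tested on it directly, and the progressive aligner is
  validated separately (optimal pairwise scores, degapping invariants,
  motif-column coherence at `mu = 0`).
- Real decarboxylase families differ in length, carry indels, and have
  backbone divergence far above 5%; passing these tests demonstrates the
  machinery is correct on its stated model, not that the thresholds are
  optimal for arbitrary real families.

`generate_citrus_like_pair()` produces the package's stand-in for the
near-identical pTDC pair from two sibling citrus genomes: two TDC-planted
500-residue sequences differing at exactly position 463 (outside every
motif window), hence 499/500 = 99.80% identity and a 4:0 TDC vote for
both.

# Alignment engine

`align_pair()` is Needleman-Wunsch/Gotoh with affine penalties; a gap of
length L costs `gap_open + L * gap_extend` (defaults BLOSUM62, 10/1 —
standard protein settings, and the exact convention of
`Biostrings::pairwiseAlignment`, which the test suite uses as an
independent oracle alongside a brute-force enumerator on tiny inputs).
Traceback ties prefer match/mismatch, then a gap in the first sequence,
then the second — determinism the tests rely on. `progressive_align()`
builds a UPGMA guide tree on `1 - identity` of all pairwise alignments
(affordable and more accurate than k-mer distances at desk scale) and
merges profiles along it; the score for pairing two profile columns is the
mean pairwise substitution score over residue frequencies, with gap
entries contributing zero (existing gaps are free; new gaps pay the affine
penalties). The DP core is shared C++ (`gotoh_core`) operating on a
precomputed column-score matrix, so the two-sequence case reduces exactly
to the pairwise optimum. There is no iterative refinement; the aim is
column-structure fidelity on desk-scale families, not reproduction of any
particular aligner's output byte-for-byte.

# Distances, NJ and bootstrap

`distance_from_alignment()` computes p-distances over pairwise shared
non-gap columns and, with `model = "dayhoff"`, the correction
`d = -ln(1 - p - 0.2 p^2)`, valid for `p < 0.8541...` (beyond that it
errors and advises `model = "p"`). Neighbor joining is the standard
Saitou-Nei agglomeration with deterministic smallest-index tie-breaks;
it is exact on additive matrices (tested against path-sum oracles and
`ape::nj`). Negative branch lengths on non-additive input are clamped to
zero with the total deficit recorded in the `clamped` attribute. NJ on
Dayhoff-corrected distances is an explicit stand-in for full
maximum-likelihood inference under a Dayhoff model: the claim being
checked — two clusters separating TDC from TYDC, with the class
bipartition at high support — is topological, and rate-uniformity and
other ML details cannot be mirrored by a distance method.

`bootstrap_tree()` resamples columns with replacement (default 100
replicates, one RNG stream per run, bit-identical given the seed),
rebuilds NJ per replicate, and scores each internal edge of the full-data
tree by the percentage of replicates containing the same leaf bipartition
(canonicalized on the side not containing the alphabetically first
taxon). Supports are internal node labels in the Newick output, the
standard dialect. Replicates whose distance computation fails (a resample
can push a pair outside the Dayhoff domain) are redrawn, capped at ten
times the replicate count. On a 6+6 planted family at `mu = 0.05` the
class bipartition reaches support 100.

# MRM transition arithmetic

The analyte series is tryptamine (C10H12N2) and its N-methyl derivatives.
Ions: `[M+H]+` for 0-2 methyls; the N,N,N-trimethyl species is a
**quaternary ammonium cation** (C13H19N2+) detected at its own m/z with no
added proton — the only model consistent with the printed precursors 203.1
and 208.1. d5 labeling replaces five indole-ring hydrogens with deuterium
(shift 5 x (m_D - m_H) = 5.0314 Da). Products arise by amine neutral
loss (ammonia, methylamine, dimethylamine, trimethylamine by methylation
count), always yielding protonated vinylindole C10H10N+ (m/z 144) or its
d5 analogue (149); the protonated trimethylamine fragment at m/z 60 is the
low-mass diagnostic.

Constants: H 1.0078250319, D 2.0141017780, C 12 (exact), N 14.0030740052;
proton 1.00727646 (electron adjustment folded in; the electron mass is
subtracted explicitly for the intact cation). **Printed values are
truncated (floored), not rounded**: exact 203.154 and 208.186 print as
203.1 and 208.1, so `precursor_mz()` floors to one decimal and
`product_mz()` floors to integers; two of the eight precursors would be
misreported under rounding. One naming quirk is preserved deliberately:
the monitored list labels the 189.1 -> 144 transition as an
"N,N-trimethyl" compound, but the mass arithmetic only fits the doubly
methylated analyte, so `transition_table()` reports it as
N,N-dimethyltryptamine. MS3 fragments (e.g. m/z 122) are out of scope —
their composition is not fixed by the transition model.

# Numerical and degenerate-input choices

- Percent identity: identical non-gap columns over columns with at least
  one residue (dual-gap columns excluded) — the convention under which one
  substitution in an ungapped 500-residue pair is exactly 99.80%. `X`
  never counts as a match. Reported to two decimals.
- ORF arithmetic: `orf_protein_length(70, 1572)` = (1503 / 3) - 1 = 500
  residues, the last codon being a stop.
- Sequences shorter than a motif scan to an empty hit list, not an error;
  classification of evidence-free sequences is `UNCLASSIFIED`.
- All stochastic entry points (`generate_family()`,
  `generate_citrus_like_pair()`, `bootstrap_tree()`) take a single integer
  seed and restore the caller's RNG state (`withr::local_seed`).

# Problem sizes

The shipped analyses and tests run at desk scale, chosen to exercise every
code path while staying quick: families of 6-8 records per class at length
500 (the reference chain length) for discovery and trees, 50 replicate
families at `mu = 0.02` for the classification-accuracy property, 20 seeds
at `mu = 0.05` for discovery recall (pooled recall >= 0.95), bootstrap at
the conventional 100 replicates, and NJ additivity up to 8 taxa against
brute-force path sums.

# Known limitations

- The progressive aligner has no iterative refinement and free in-profile
  gaps; on noisy families it can prefer a gapped alignment where the
  planted coordinates were gapless (the discovery drivers report recall
  against ground truth honestly when this happens).
- Discovery has no null model: reported motif pairs are descriptive, not
  significance-tested.
- The catalog ships accessions and class labels only, not sequences;
  classifying the real database entries requires fetching them (see the
  README), which the offline test suite does not do.
- NJ + Dayhoff distances approximate, but are not, an ML/Dayhoff tree.
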