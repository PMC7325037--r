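---
title: "Methods: classifying, annotating and screening Tc1/mariner transposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying, annotating and screening Tc1/mariner transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmariner)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data validation does and does not
demonstrate about real data.

## The classification model

Tc1/mariner (ITm) transposases carry a catalytic triad of two aspartates
and a third aspartate or glutamate (DDD/E). Families are distinguished by
the residue count strictly between the second and third catalytic
positions: the signature `DD34E` means 34 residues sit between the second D
and the E. The package fixes the spacing convention as
`spacing = pos3 − pos2 − 1` in ungapped query coordinates; an off-by-one
here would corrupt every downstream family call, so it is pinned by tests
on planted triads. The interval between the first and second positions is
reported (`spacing12`) but never used for classification.

Signatures map to candidate families by lookup: DD34D → mariner; DD34E →
{Tc1, Tec, TBE, HvSm}; DD39D → PlantMar; DD37D → maT; DD41D → rosa; DD37E →
{TRT, impala, DD37E(L31)}; any other DD(30–35)D → pogo; everything else →
unknown. Two deliberate choices: ambiguity is **never** silently resolved —
DD34E returns the full four-family set because those families separate only
phylogenetically — and degenerate residues at catalytic positions (DA30P,
DD34S and similar patterns typical of domesticated, host-exapted copies)
are reported verbatim with a flag rather than rejected. The lookup places
DD34D with mariner even though a few pogo subgroups also show DD34D; that
finer resolution requires clade membership in the tree, not the signature
alone.

## Locating the triad

The primary detector aligns a query to a *seed profile*: a fixed gapped
alignment of reference transposase domains in which the three catalytic
column indices are known. The alignment is a sequence-to-profile dynamic
programme against per-column residue frequencies (scores are
frequency-weighted BLOSUM62 values) with affine gaps (open 10, extend 0.5;
a gap of length L costs `open + L·extend`). Profile columns are immutable:
the query either maps a residue to a column or records an insertion between
columns. Catalytic residues are read at the catalytic columns and mapped
back to ungapped query positions, so insertions between columns 2 and 3
correctly enlarge the spacing, and a deletion at a catalytic column
produces an explicit no-call rather than a shifted residue. A brute-force
de novo scanner (`detect_motif_denovo`, all position triples with allowed
residues and an admissible spacing) serves as a fallback and as the oracle
target in tests; on realistic sequence lengths it finds many spurious
triads, which is exactly why the profile route is the default.

The shipped profile (`inst/extdata/synthetic_seed_profile.afa` plus its
YAML sidecar naming the catalytic columns) is synthetic — generated by
`sim_family()` — because the package bundles no third-party alignment; any
real seed alignment can be supplied through `read_seed_profile()`.

## Element annotation

`annotate_element()` composes three detectors, all in 1-based closed
coordinates (the native R/Bioconductor convention, used consistently at
every interface):

* **ORFs**: every ATG to its next in-frame stop, all six frames, reported
  with the stop codon included and filtered by a minimum codon count
  (default 50). Nested starts each count; ORFs lacking a stop are not
  reported.
* **TIRs**: a terminal-anchored comparison of the first `window` bases
  against the reverse complement of the last `window` bases. Each arm may
  shift at most `slack` (default 5) nt from its terminus, arms are compared
  ungapped, identity is matches over compared length (the repo-wide
  single identity definition: denominator includes all compared columns),
  and the score is matches − mismatches with ties going to the longer TIR,
  then the 5'-most. A genome-wide palindrome scan is deliberately out of
  scope: excised elements have their TIRs at the termini by definition.
  Defaults (min length 10 nt, min identity 80%) are loose enough to admit
  the short 15 bp TIRs reported for compact elements. Whether reported TIR
  lengths in the literature allow internal mismatches is often unstated;
  the identity threshold covers both readings.
* **TSD**: the last two nt of the 5' flank must equal the first two nt of
  the 3' flank; the ITm target-site duplication is "TA", and the check
  flags `is_ta` separately so non-TA duplications remain visible.

## Copy census

Genome hits for one element are clustered into loci by single linkage on
the subject (same scaffold and strand, subject intervals within `max_gap`,
default twice the element length), then each locus is classified with
inclusive thresholds, in precedence order:

1. full-length — any hit with identity ≥ 95% covering ≥ 95% of the element;
2. MITE — hits at ≥ 95% identity whose query intervals jointly cover both
   TIR intervals (one spanning hit or two separate TIR hits both qualify —
   the wording of the source procedure admits either reading);
3. partial — identity ≥ 80% over ≥ 50%;
4. non-autonomous — identity ≥ 50% over ≥ 25%;
5. otherwise unclassified.

MITE sits above partial because TIR-specific evidence is the more specific
claim and a MITE locus can incidentally satisfy the partial rule. Coverage
for classes 1, 3 and 4 uses the single best hit's span (the procedure
speaks of "a scaffold hit", singular); only the MITE rule unions intervals,
and its identity is the minimum over the TIR-overlapping hits
(conservative). Counts always sum to the number of loci.

## Phylogeny

Trees are `ape::phylo` objects throughout, and externally computed Newick
trees are first-class inputs (`parse_newick()`), so a maximum-likelihood
tree from a dedicated tool can replace the built-in engine at any stage.
The native engine is deliberately desk-scale: p-distances with pairwise
deletion of gap columns, canonical neighbor-joining with two pinned
numerical choices — Q-criterion ties broken by the smallest index pair in
agglomeration order, and negative branch lengths clamped to zero with the
deficit moved to the sister branch so the joined pair's path length is
preserved — and a column-resampling bootstrap from a single seeded
generator (support = percentage of replicate trees containing the same
bipartition). On additive matrices NJ provably recovers the generating
tree, which the tests exercise; `ape::nj` serves as an independent
cross-check, never as the implementation.

Rooting uses an outgroup (IS630-style sequences in the demonstration): the
root lands on the edge separating the smallest clade holding all outgroup
leaves, with that edge's length split evenly. A non-monophyletic outgroup
is still rooted — on the edge maximising outgroup purity × completeness —
but flagged. Clade extraction then returns the *maximal* clades with
support at or above the threshold (default 70%) whose parent is not itself
such a clade; leaves outside every group are reported as isolated. One
consequence worth knowing: with a supported outgroup split, the whole
ingroup is a legitimate maximal clade, so family-level structure is read
either from deeper thresholds or directly from monophyly checks.

## Tanglegram congruence

The host tree is the taxonomy table's rank hierarchy (kingdom → species;
no host molecular tree is assumed). Crossings between the TE tree and the
host tree are counted as strict inversions of the link permutation
(mergesort), and minimised by alternating barycenter sweeps over each
tree's internal-node rotations, refined by hill climbing over child
permutations — singly, then in pairs, with paths re-mapped when two moves
act on the same tree — from four deterministic starts (original and
mirrored rotations). Accepted moves must strictly reduce crossings, so the
count never increases, and the reported statistic,
`crossings / C(n_links, 2)`, is 0 for perfectly codiverging histories and
grows with horizontal transfer. Each element contributes one unit-weight
link to its host; weighting multiple elements per host differently is a
possible extension, not implemented.

## Horizontal-transfer screen

Pairs of elements are evaluated only when their hosts differ at or above a
configurable taxonomy rank (default phylum — "distantly related" hosts at
kingdom or phylum level are the interesting cases; anything closer is
plausibly vertical). For each evaluated pair the screen computes the amino
acid identity of the DDE domains (catalytic span of the transposase, taken
from the longest ORF with a locatable triad), the nucleotide identity of
the transposase ORFs, and — when both elements carry TIR-to-TIR sequence —
the full-element nucleotide identity, all as global-alignment identities
with gaps in the denominator (EMBOSS-style, which matters because the
thresholds below were calibrated under that convention). The decision
table, in order: genome unavailable → unverifiable; any genome with a
single locus → rejected (contamination suspect); copies below 92% identity
in both genomes or full-element identity below 80% → rejected (divergent);
copies ≥ 95% in one genome but < 95% in the other → rejected (asymmetric,
contamination suspect); otherwise candidate. The 92% and 80% figures are
treated as observed rejection conditions of the published screening
procedure, not tunable constants; tightening any threshold can only move
pairs out of candidacy, a monotonicity property the tests check.

## Synthetic data: what it validates

Every generator takes one seed, is byte-reproducible, and emits a
machine-readable truth table; recovery tests read the truth, never
re-derive it. Design choices favour testability over realism where the two
conflict:

* catalytic triad sites are immutable under simulated divergence, so motif
  ground truth is a construction guarantee;
* substitutions are i.i.d. uniform over alternatives — no rate
  heterogeneity, no indels (except the indels planted explicitly between
  catalytic positions for the reference-style sequences);
* `sim_element` pins the bases just inside each spacer to be
  non-complementary, so the planted TIR length is the detector's unique
  optimum rather than merely its most likely answer;
* `mutate_element_bases` repairs premature stop codons after mutation, so
  benchmark elements keep a readable transposase the way selection keeps
  real active copies readable;
* hit-table generators draw identities and coverages inside each class
  band, with an option to sit exactly on the thresholds to exercise
  boundary inclusivity.

Default conditions mirror a compact ITm element: 20 bp TIRs, TA TSDs, a
756 bp transposase ORF in an 1841 bp element; transposase families default
to 340-residue proteins with a DD34E triad; the cophylogeny generator uses
16 hosts on a binary kingdom/phylum/class/order hierarchy with protein
evolution at 6% per site per level and transfers implanted as recent
(2% diverged) cross-kingdom copies.

Passing on these simulations demonstrates that the *procedures* are
implemented correctly — thresholds inclusive, spacings exact, counts
conserved, statistics monotone in the planted signal. It does not
demonstrate performance on real data, where alignment error, nested and
fragmented insertions, rate heterogeneity, and assembly artefacts (e.g.
duplicate WGS submissions, which the census tests show would double every
count) all bite. The problem sizes used throughout (tens of sequences,
hundreds of columns, 20–100 bootstrap replicates in examples) were chosen
as the smallest sizes at which every property is informative; all scale
parameters are arguments.

## Known limitations

* The profile aligner is per-column frequency based; it does not model
  column-specific gap penalties or use an HMM, so very remote homologues
  may misalign — the no-call path and the de novo fallback exist for that
  reason.
* The mining loop's novelty rule (single-linkage clusters below the
  novelty identity against all prior queries) is a deterministic, tree-free
  proxy for what is in practice a manual inspection of a preliminary
  phylogeny.
* Crossing minimisation is heuristic; on small instances it matches
  exhaustive enumeration in ≥ 95% of random cases (tested) but carries no
  optimality guarantee.
* The HTT screen's verdicts inherit every upstream assumption (ORF
  integrity, locatable triads, trustworthy hit tables); on real data its
  output is a shortlist for manual verification, not a final call.
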