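# tcmariner

Characterisation of Tc1/mariner (ITm) DNA transposons in R: catalytic-motif
family classification, element structure annotation, copy-number census,
phylogeny with host-congruence statistics, and a horizontal transposon
transfer (HTT) screen — with synthetic-data generators that make the whole
pipeline testable end to end without any external database.

## The problem and who this is for

Tc1/mariner elements are cut-and-paste DNA transposons found across
eukaryotes. Their families are recognised by the geometry of the
transposase's catalytic triad — two aspartates and a third aspartate or
glutamate (DDD/E) — and named by the number of residues strictly between
the second and third positions: `mariner` is DD34D, `Tc1` is DD34E,
`PlantMar` DD39D, `maT` DD37D, `rosa` DD41D, `pogo` DD(30–35)D, and so on.
Around that classification sit several standard analyses: filtering
homology-search hits (retain ≥ 50% identity over ≥ 50% of the query),
annotating element structure (terminal inverted repeats, TA target-site
duplications, the transposase ORF), counting genome copies per class
(full-length ≥ 95%/95%, partial ≥ 80%/50%, non-autonomous ≥ 50%/25%, MITEs
≥ 95% over both TIRs), building a bootstrapped phylogeny rooted with the
bacterial IS630 outgroup, measuring TE-versus-host tree incongruence with a
tanglegram, and screening candidate horizontal transfers with contamination
heuristics. This package implements each step as a tested R function, for
anyone studying DNA-transposon diversity who wants those procedures
reproducible and scriptable.

## Core quantities

* **Motif signature** `res1 res2 <spacing> res3`, where
  `spacing = pos3 − pos2 − 1` in ungapped query coordinates. Read off a
  sequence-to-profile alignment against a seed DDE-domain alignment whose
  three catalytic columns are known; insertions between columns count
  toward the spacing, a deleted catalytic column is a no-call.
* **Copy classes** per locus (single-linkage clusters of genome hits), with
  inclusive thresholds and precedence full-length → MITE → partial →
  non-autonomous.
* **Congruence statistic**: link crossings of the TE/host tanglegram after
  crossing minimisation (alternating barycenter sweeps plus rotation hill
  climbing), normalised by the number of link pairs.
* **HTT decision table**: pairs of elements from hosts differing at or
  above phylum rank are `candidate` unless a genome shows a single copy
  (contamination suspect), copies are ≥ 95% identical in one genome but
  < 95% in the other (asymmetry), or identities fall below 92% (copies) /
  80% (full element) — then they are rejected.

## Worked example

```r
library(tcmariner)

# a transposase family with a planted DD34E triad, and its seed profile
fam  <- sim_family(n = 10, spacing = 34, third = "E", divergence = 0.1, seed = 1)
prof <- sim_seed_profile(fam)
classify_motifs(fam$seqs[1:3], profile = prof)
#>        id signature spacing       candidates degenerate found
#> 1 fam_001     DD34E      34 Tc1,Tec,TBE,HvSm      FALSE  TRUE
#> 2 fam_002     DD34E      34 Tc1,Tec,TBE,HvSm      FALSE  TRUE
#> 3 fam_003     DD34E      34 Tc1,Tec,TBE,HvSm      FALSE  TRUE

# a full-length element: 20 bp TIRs, TA TSDs, 756 bp transposase ORF
el  <- sim_element(seed = 5, plant_triad = TRUE)
ann <- annotate_element(el$bases, el$id, el$flank5, el$flank3)
ann$tir$length        # 20
ann$tsd               # $tsd "TA", $is_ta TRUE

# census of a simulated genome hit table
sim <- sim_hit_table(nchar(el$bases),
                     tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3),
                     counts = c(full = 3, partial = 2, mite = 4, nonaut = 2),
                     seed = 2, query_id = el$id)
census(sim$hits, nchar(el$bases), tir = ann$tir)
#>    full_length           mite        partial non_autonomous   unclassified
#>              3              4              2              2              0
```

The `DD34E` signature stays a candidate set (`Tc1,Tec,TBE,HvSm`) because
those families share the signature and are separated only phylogenetically;
the census counts equal the generator's planted truth.

A complete narrative run — simulation, motif classification, census,
bootstrapped NJ phylogeny with IS630-style outgroup rooting, tanglegram,
HTT screen — lives in the numbered drivers under `analysis/` (they write
their tables under `results/`):

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

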