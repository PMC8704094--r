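---
title: "Models and methods behind barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

`barcodegap` implements the three analyses a taxonomist combines when
delimiting fungal species with a dual ITS / tef1-α barcode: the K2P
barcoding gap, the CBC species concept on the ITS2 secondary structure, and
exact-match assignment of environmental spacer reads. This vignette records
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
design decisions that were genuinely open.

## Distances and the barcoding gap

Pairwise distances use the Kimura two-parameter model,

$$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with `P` and `Q` the transition and transversion proportions over the
compared sites. Columns holding a gap or `N` on either row are excluded
pair by pair (*pairwise deletion*); a *complete deletion* switch exists for
sensitivity checks in MSA mode. When the log argument is non-positive
(saturation) the distance is reported as an explicit undefined value — it
is masked in matrices and counted in partition reports, never dropped
silently or turned into an error, because a single saturated pair should
not abort a genus-level analysis.

Two computation modes exist because the two use cases differ:

* `mode = "pairwise"` aligns each pair on its own with Needleman–Wunsch
  (affine gaps, via Biostrings). Defaults `match = 1`, `mismatch = -1`,
  `gap_open = -2`, `gap_extend = -0.5`: near-identical barcode pairs — the
  regime every gap analysis lives in — are insensitive to these values, and
  they are echoed in every report so a run is reproducible from its output.
* `mode = "msa"` consumes rows of a shared multiple alignment unchanged.
  Genus-level matrices should use this mode, matching how distance matrices
  are computed from curated alignments in practice.

The *barcoding gap* of a labeled distance set is the open interval between
the largest intraspecific and the smallest interspecific distance; it is
overlapping (absent) when that width is non-positive. Distances are kept as
fractions internally; reports print percentages rounded half-even to one
decimal, the precision at which such values are published. Extreme species
pairs are computed per strain pair (the per-species-pair minima and maxima,
then the global extrema), since species-centroid versions hide which strains
drive the extremes; both min and max are reported per species pair in
`tidy()` output.

Histogram bins start at 0 and are right-closed, left-open with the first
bin closed at 0. The convention is arbitrary but must be deterministic for
reproducible counts; right-closed was chosen so a distance exactly on an
edge joins the bin it ends. Bin widths of 0.001, and 0.0005 for
low-divergence genera, match the scale of K2P barcode distances.

## ITS2 substitution classes and the CBC species concept

Structure work happens in RNA space (`T` is read as `U` on entry). A base
pair state is *canonical* (G=C, C=G, A-U, U-A), *wobble* (G/U, U/G and the
protonated A⁺/C in both orientations), *noncanonical* (any other A/C/G/U
combination) or *gapped* (any gap or `N`). Whether both orientations of A/C
count as wobble is configurable (`ac_wobble`), because published treatments
are not explicit about orientation; the default includes both.

Comparing one structural pair between two species yields exactly one class:

* `identical` — nothing changed;
* `CBC` — both partners differ and both states are canonical;
* `hCBC` — exactly one partner differs, converting canonical ↔ wobble
  (the only single-base change possible between paired categories);
* `nonCBC` — either state is noncanonical;
* `combined` — both partners differ between paired categories without being
  canonical → canonical (e.g. G=C → U/G). These doubles decompose into an
  hCBC plus a second event; they get their own class rather than being
  forced into hCBC or nonCBC so reports can list the decomposition;
* `indeterminate` — either state gapped.

The classification is total and deterministic over all 16×16 ACGU pair
transitions, and the test suite pins it to an exhaustively enumerated
fixture. Event enumeration runs species-vs-species by default; a
species-vs-reference mode exists because published counts do not always say
which convention they use, and the report names the mode. Species with
several distinct ITS2 sequences are collapsed to a majority-rule consensus
first (ties become `N`, and the species is flagged), since the CBC concept
compares species-level sequences. Differences at unpaired columns are
tallied separately as single mutations in hairpin loops and junction areas.

A species is CBC-supported when it shows at least one CBC against every
other congener in the table — the operational reading of the CBC criterion
for mostly asexual fungi, where the criterion is assessed independently of
observed mating.

Structures are consumed, never predicted: the dot-bracket parser builds the
pair map by bracket matching and assigns each pair to the helix span
containing its 5′ position (H1–H3 in the ring model; H4 is absent in the
genera this package targets). A projection helper moves an ungapped
reference structure onto alignment coordinates, turning reference-gap
columns into unpaired positions. Coordinates are 1-based closed intervals
everywhere in documentation and reports.

## Exact-match environmental assignment

The reference is a per-(species, spacer) haplotype table; identical
sequences collapse, and haplotypes shared across species are kept in both
cells so the screen can flag them. Distinctiveness is the minimum number of
differing positions over cross-species haplotype pairs under an
end-gap-free comparison. One corner case was resolved deliberately: when
one haplotype is a terminal extension of the other with no internal
difference, the end-gap-free count would be 0 even though the haplotypes
are not interchangeable under exact matching; the terminal length
difference is reported instead, so `min_diff == 0` exactly when an
identical haplotype is shared (the nested-haplotype rule).

Matching follows the 100 % similarity, full-length-coverage rule: a query
is assigned only if it equals a reference haplotype over its whole length.
The reference may exceed the query by at most `trim_tol` bases at the 5′
end — default 2 for ITS2 and 0 for ITS1, because database ITS2 spacers
usually lack 1–2 bp at the 5′ end while ITS1 spacers do not show that
defect — and there is no 3′ slack (the trimming rationale concerns only the
5′ end of ITS2; the interpretation is a configuration switch). `N`
mismatches everything, including `N`, since an ambiguous base cannot attest
100 % identity. Queries matching haplotypes of k ≥ 2 species are flagged
`ambiguous` and excluded from species summaries by default (species links
should be unequivocal); an include-ambiguous mode exists for sensitivity
analysis.

Per-species summaries report sample counts, substrate and biome
proportions, means of MAT (°C) and MAP (mm) over defined values, and
Köppen-Geiger zone tallies (climate labels are consumed as metadata; no
raster lookup). The distribution type uses a threshold rule the source
vocabulary implies but does not quantify: *tropical* when ≥ 80 % of samples
fall in tropical zones (Köppen group A), *temperate/continental* when
≥ 80 % fall in C+D zones, otherwise *global*. The thresholds are
configurable and echoed in reports.

## Synthetic data: what it emulates, what it does not

`simulate_genus()` uses a star-within-star design: species ancestors evolve
independently from a genus root at `inter_d` each, strains from their
ancestor at `intra_d / 2` each. Intraspecific pairwise distances therefore
concentrate around `intra_d`, and interspecific ones around
`2·inter_d + intra_d`, so the minimum interspecific distance stays above
the `inter_d` floor — the regime a clean barcoding gap requires. Defaults
(4 species × 3 strains, 600 bp ITS-like length, `intra_d = 0.002`,
`inter_d = 0.02`, κ = 2) mirror the divergence regime of well-sampled
hyphomycete genera, where intraspecific ITS variation sits well below 0.5 %
and interspecific divergence above 2 %.

`evolve_k2p()` implements the K2P process with per-site rates α
(transitions) and β (each transversion), κ = α/β, and the branch length
solved from the target distance through the K2P expectation
(`d = (α + 2β)t`). Plugging the expected change probabilities into the K2P
estimator returns exactly `d`, which is what makes "target distance"
well-defined rather than a raw substitution count. Saturation is rejected
when the expected log argument falls below 10⁻¹², i.e. when the target is
numerically indistinguishable from a saturated pair.

`plant_structure_events()` changes exactly the requested base pairs and
nothing else (each event uses its own pair), so enumeration has exact
planted truth. `simulate_env_reads()` draws reads as haplotypes with
sampled 5′ truncations (default 0/1/2 bp with probabilities 0.4/0.3/0.3,
centred on the "usually 1–2 bp missing" regime), decoys rejection-sampled
to differ from every haplotype and every allowed trim of it, and metadata
from per-species categorical and normal models whose parameters are
recorded in the truth object. The default metadata model alternates a
tropical profile (zones Af/Am/Aw, MAT ~ N(24, 2) °C, MAP ~ N(2600, 300) mm)
with a temperate/continental one (Cfb/Dfb, MAT ~ N(10, 3), MAP ~ N(900,
200)), the two dominant distribution types among the target genera.

What the generators deliberately do **not** emulate: indel processes
(alignment quality is not the object under test, so simulated sets are
gap-free and columns stay homologous), coalescent tree shape within
species, intragenomic ITS variation, chimeras, and sequencing error beyond
the 5′ truncation. Passing tests therefore demonstrate the correctness of
the counting, classification and matching machinery under the stated
statistical structure — not robustness to misalignment or to noisy reads,
which real data add on top.

All generators are deterministic under an integer seed (R's default
Mersenne-Twister, seeded locally so the session RNG is untouched).

## Numerical choices and degenerate inputs

* Undefined distances: `NA` with a mask, never an exception; partitions
  count exclusions.
* Saturation boundary: tested at exactly representable P/Q values; the
  implementation flags `(1 − 2P − Q) ≤ 0` or `(1 − 2Q) ≤ 0`.
* Histogram edge assignment uses a 10⁻⁹-relative guard so distances
  computed to the edge value in floating point land deterministically.
* Empty intra or inter sets give flagged, undefined gap bounds; a single
  species is a valid input to the gap stage.
* Spacer delimitation: one missing anchor yields a flagged best-effort
  spacer open at that end; both anchors missing marks the spacer
  undelimited with `NA` residues. Anchor motifs default to conserved
  fungal rRNA primer-region motifs with a per-motif mismatch tolerance
  of 1, and both motifs and tolerance are configurable, since boundary
  definitions differ slightly between delimitation tools; ±2 bp boundary
  shifts should be expected when comparing against other extractors.
* Alignment traceback is Biostrings' deterministic one; determinism (the
  property tie-break rules exist for) is tested directly.

## Problem sizes in the test and acceptance runs

The suite checks the K2P implementation against an independent
count-and-formula oracle on 1,000 random gapped pairs (agreement to
10⁻¹²), estimator recovery at d ∈ {0.01, 0.05, 0.13} with 200 replicates of
10,000 bp, planted-event recovery and gap detection over 50 seeded runs
each, and matching semantics on planted environmental sets with shared-ITS1
species pairs, 1–2 bp truncated ITS2 reads and decoys. Gap-detection runs
use 10,000 bp sequences — the same scale as the estimator-recovery checks —
so that sampling error in the distance estimate (≈ √(d/L) ≈ 4·10⁻⁴) cannot
blur the planted gap; at ITS-like lengths the same machinery runs
identically but extreme-value noise across 66 pairwise estimates would
occasionally cross the planted bounds, which would test the generator's
noise level rather than the analysis.

## Known limitations

* Alignment-free truth: the distance stage trusts its alignments; badly
  misaligned inputs produce distances whose failure mode is saturation, not
  a warning.
* The CBC stage consumes a single consensus structure per genus; species
  whose true structure deviates from the consensus are classified against
  the wrong pair map.
* Exact matching cannot see haplotypes absent from the reference;
  recall against real environmental data is bounded by reference
  completeness, which no synthetic test can measure.
* The distribution-type rule is a threshold heuristic; species with
  strongly clustered sampling effort can be mislabeled by sampling bias
  alone.
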