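# barcodegap

Dual-barcode species delimitation and biogeography tools for fungi, built
around the three molecular lines of evidence mycologists combine when
splitting genera of dematiaceous hyphomycetes:

1. **Barcoding-gap analysis.** Pairwise Kimura two-parameter (K2P) distances
   of ITS and tef1-α sequences are partitioned into intraspecific and
   interspecific sets; the *barcoding gap* is the open interval
   `(max d_intra, min d_inter)`. The K2P distance corrects observed
   divergence with separate transition (P) and transversion (Q) proportions:

   d = −½ · ln( (1 − 2P − Q) · √(1 − 2Q) )

2. **The CBC species concept.** Substitutions at base pairs of the ITS2
   secondary structure (a ring with conserved helices H1–H3) are classified
   as compensatory (CBC: both partners change, canonical pair to canonical
   pair, e.g. G=C → C=G), hemi-compensatory (hCBC: one partner changes,
   canonical ↔ wobble, e.g. G=C → G/U) or non-compensatory (non-CBC: the
   result is a non-canonical pair). A species showing at least one CBC
   against every congener is corroborated as a separate biological species.

3. **Exact-match environmental assignment.** Reference ITS1/ITS2 haplotypes
   are screened for per-spacer distinctiveness (some species pairs share an
   identical ITS1 and are only separable by ITS2), then environmental reads
   are assigned under a 100 % identity, full-length-coverage rule, allowing
   1–2 bp of 5′ truncation of ITS2 — the defect environmental spacers
   typically carry. Assigned samples are summarised into per-species
   biogeographic profiles (substrate, biome, Köppen-Geiger climate zones,
   MAT/MAP means, distribution type).

A seeded synthetic-data generator reproduces the statistical structure each
stage assumes (a star-within-star K2P genus simulator, a structural-event
planter, an environmental-read simulator with metadata models), so the whole
pipeline runs and is tested without any downloads.

The package is tidyverse-native: every user-facing function takes a data
frame and returns a tibble, results have `tidy()`/`glance()` methods and
`autoplot()` figures, and the three `run_*()` stage drivers write
reproducible report bundles from a YAML or list configuration.

## Worked example

Simulate a four-species genus (three strains each, ITS-like 600 bp,
intraspecific distance 0.2 %, interspecific well above 2 %), then run the
gap analysis:

```r
library(barcodegap)

sim   <- simulate_genus(n_species = 4, strains_per_species = 3, length = 600,
                        intra_d = 0.002, inter_d = 0.02, seed = 11)
dists <- pairwise_distances(sim$sequences, mode = "msa")
part  <- partition_distances(dists, sim$species_map)
gap_report(part)
#> <gap_report>
#>   max intraspecific: 0.3341% (n = 12)
#>   min interspecific: 2.895% (n = 54)
#>   gap: (0.3341%, 2.895%), width 2.561%
```

The 12 intraspecific distances stay below 0.4 %, the 54 interspecific ones
never drop under 2.9 %: a clean barcoding gap. The closest and most
divergent species pairs (the numbers barcode studies print as the lowest and
highest interspecific divergence):

```r
extreme_pairs(part)
#> # A tibble: 2 × 7
#>   extreme speciesA   speciesB   idA           idB           distance percent
#> 1 min     Species_02 Species_03 Species_02_s1 Species_03_s2   0.0289     2.9
#> 2 max     Species_01 Species_04 Species_01_s1 Species_04_s1   0.0482     4.8
```

Classifying ITS2 base-pair substitutions is a one-liner:

```r
classify_pair_change(c("GC", "GC", "AU"), c("CG", "GU", "AA"))
#> [1] "CBC"  "hCBC" "nonCBC"
```

`autoplot(gap_histogram(part, 0.001))` draws the intra/inter histogram,
`enumerate_events()` + `cbc_species_support()` run the CBC analysis against
a dot-bracket structure, and `build_reference()` → `distinctiveness()` →
`assign_dataset()` → `summarize_species()` is the environmental-assignment
chain. `run_barcode_analysis()`, `run_structure_analysis()` and
`run_metabarcode()` drive each stage from a config file and write TSV/JSON
report bundles.

See `vignettes/barcodegap-methods.Rmd` for the models, parameter choices and
limitations.

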