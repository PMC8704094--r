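Package: barcodegap
Title: Dual-Barcode Species Delimitation for Fungal ITS and tef1-alpha Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-barcode based species delimitation and biogeography
    of dematiaceous hyphomycetes and other fungi. Implements Kimura
    two-parameter (K2P) barcoding-gap analysis of ITS and tef1-alpha sequences
    (distance partitions, gap reports, histograms, extreme species pairs),
    secondary-structure-aware classification of ITS2 substitutions into
    compensatory (CBC), hemi-compensatory (hCBC) and non-compensatory classes
    for the CBC species concept, and an exact-match assignment workflow for
    environmental ITS1/ITS2 reads with per-spacer distinctiveness screening and
    per-species biogeographic summaries. A seeded synthetic-data generator
    reproduces the statistical structure of each analysis stage so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
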