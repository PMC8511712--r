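Package: taxadiel
Title: Diel Rhythmicity and Pathway Timing in Taxon-Binned
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing diel (24-hour) periodicity in eukaryotic
    community metatranscriptomes sampled on a regular time-of-day grid.
    Builds environmental taxon bins from annotated contigs, computes
    bin-denominated FPKM, scores bin completeness against a core
    gene-family set, detects rhythmic gene families with a nonparametric
    umbrella rank test under a permutation null with Benjamini-Hochberg
    FDR control, tests pathway-by-time enrichment with one-sided Fisher
    exact tests, and ordinates community profiles with Bray-Curtis NMDS.
    Ships a fully parameterised synthetic diel metatranscriptome
    generator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
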