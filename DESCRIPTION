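Package: VDACmods
Title: PTM Site Mapping and Single-Channel Analysis for Mitochondrial Porins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bottom-up proteomics mapping of post-translational
    modifications (oxidation, deamidation, succination, succinimide
    formation) on mitochondrial outer-membrane channel proteins, together
    with planar-lipid-bilayer single-channel analysis. Provides in-silico
    trypsin/chymotrypsin digestion with missed cleavages and isoform-aware
    sequence coverage, monoisotopic peptidoform mass and m/z arithmetic
    with a curated modification registry, b/y fragment ladders with
    diagnostic neutral losses (including the 64 Da methanesulfenic acid
    loss of methionine sulfoxide), tolerance-based MS/MS peak annotation,
    label-free intensity-ratio quantification of modified versus reference
    site states across technical replicates, and conductance / voltage
    dependence analysis of single-channel current recordings. Synthetic
    generators emulate evidence tables, MS/MS spectra and gating traces so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
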