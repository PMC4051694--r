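Package: icplquant
Title: Quantitative Shotgun Proteomics with Isotope-Coded Protein Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of a quantitative shotgun-proteomics
    workflow for cyanobacteria grown under diel (light/dark) cycles.
    Provides in-silico tryptic digestion, peptide-spectrum-match filtering
    with target-decoy false-discovery-rate estimation, emPAI protein
    abundance estimation, multi-fractionation coverage accounting (Venn
    arithmetic across separation workflows), quantification of paired
    light/heavy extracted-ion chromatograms from post-digest ICPL labeling
    (Pearson pair matching, Simpson integration, median normalization,
    log-space protein rollup with a significance-versus-unity Student test,
    dual fold-change thresholds, replicate combination), and
    spectrophotometric phycocyanin and chlorophyll quantitation. A
    synthetic-data generator produces ground-truth proteomes, PSM tables
    and co-eluting Gaussian XIC pairs so the whole pipeline is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
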