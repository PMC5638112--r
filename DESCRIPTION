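Package: hybridCNV
Title: Copy-Number Variation Analysis for Hybrid-Origin Lineages from
    aCGH, Repeat Read Counts and Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting copy-number variation in an
    admixed (homoploid hybrid) lineage relative to its two parental
    species. Covers dilution-series calibration of two-colour
    comparative genomic hybridization (aCGH) arrays with per-probe
    linear response fits and quality filtering, spatial artifact
    masking and replicate summarization, LOESS normalization of log2
    ratios, rank-based group tests with Benjamini-Hochberg FDR control
    and log2-threshold calls for gene-level CNV, counts-per-million
    comparison of repetitive-element abundance with parental-bias
    decomposition and classification summaries, and Poisson-corrected
    droplet digital PCR copy-number estimation with a de novo variant
    screen. A fully parameterised synthetic-data generator reproduces
    the statistical structure of every input so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
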