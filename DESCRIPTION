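Package: silacsig
Title: Quantitative SILAC Analysis of Receptor Signalosomes and PTM Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of triple-SILAC (stable isotope labeling by amino
    acids in cell culture) experiments that follow receptor signaling over
    two stimulation time points: empirical-background scoring of
    affinity-purified signalosome interactors (median + k*SD cutoffs on
    log2 ratios with replicate-support filtering), confidence filtering and
    up/down regulation calling for phosphorylation and di-Gly
    (ubiquitylation) site tables, rule-based temporal dynamics classes,
    residue-class statistics, protein-level integration of phosphorylation
    and ubiquitylation, and hypergeometric annotation-term enrichment. A
    synthetic-data generator with ground-truth labels makes every stage
    testable without access to raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
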