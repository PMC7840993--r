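Package: tmshift
Title: Fluorescence Thermal Shift Analysis of Protein-DNA Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing fluorescence-based thermal shift assays
    (differential scanning fluorimetry) of protein-ligand and protein-DNA
    interactions. Estimates melting temperatures from dye-fluorescence melt
    curves by smoothed positive-derivative peak detection, fits the quadratic
    ligand-depletion isotherm to melting-temperature shifts to recover the
    maximal shift and an apparent dissociation constant, fits four-parameter
    logistic dose-response curves for inhibitor IC50 determination, screens
    candidate protein probes by Kyte-Doolittle hydropathy, and ships a seeded
    two-state melt-curve simulator so every pipeline stage can be validated
    by parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    minpack.lm,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
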