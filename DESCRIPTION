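Package: MORpharm
Title: Quantitative Pharmacology of Mu-Opioid Receptor Agonists
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for the bespoke quantitative procedures used in
    mu-opioid receptor (MOR) agonist pharmacology: three-parameter logistic
    concentration-response fitting with DAMGO-referenced normalization,
    radioligand association/dissociation kinetics and Cheng-Prusoff affinity
    conversion, per-timepoint BRET functional kinetics with a transduction-index
    bias calculus and full error propagation, APEX proximity-labelling
    time-course scoring (cubic-polynomial rank-time model with batch terms and
    F tests) and spatial-reference deconvolution by nonnegative least squares,
    two-channel fibre-photometry processing (isosbestic rescaling, dF/F,
    prominence-thresholded transient detection, slow-component AUC), and scalar
    pharmacological endpoint calculators such as percent maximum possible
    effect, ED50, SUV, unbound concentrations, brain/plasma ratios and
    opioid-withdrawal scoring. Seeded synthetic data generators emulate every
    input family with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    pracma,
    signal,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Proteomics, Pharmacology, Software, TimeCourse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
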