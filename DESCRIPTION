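Package: phshock
Title: Intracellular pH Dynamics and the Heat Shock Response from Flow
    Cytometry and Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how transient intracellular
    acidification gates the Hsf1-mediated heat shock response in budding
    yeast. Provides ratiometric pHluorin calibration (four-parameter
    sigmoid fit and effective pKa), conversion of per-cell 405:488
    excitation ratios to intracellular pH, deterministic flow-cytometry
    gating (scatter, BV421 exclusion, labeled vs spike-in strain
    splitting), sigmoid induction-kinetics fitting for chaperone
    fold-change time courses, two-component Gaussian-mixture
    classification of expression level and budding state with posterior
    cutoffs, competitive-fitness (selection-coefficient) estimation from
    labeled:spike-in count ratios, and regulon-level pH-sensitivity
    scoring from transcripts-per-million expression tables. A synthetic
    data module generates every input type with known ground truth so all
    estimators can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
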