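Package: nirmargin
Title: Simulation and Margin Calling for Microwell-Array NIR
    Fluorescence Tumor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and analysis of a near-infrared
    fluorescent-protein (NIR-FP) tumor-margin detection workflow: covalent
    dye-protein labeling kinetics with temperature/time/stoichiometry
    effects, molecular-weight fractionation of labeled lysates into a
    z-stack of gel layers, microwell-array imaging with optical blur and
    noise, and per-well tumor-to-reference ratio analysis with ROC/Youden
    cutoff selection, contour extraction and similarity scoring against
    ground truth. Includes a seeded synthetic tissue-phantom generator,
    chemoproteomic candidate filtering (fold-change and mass-window rules,
    multi-sample Venn analysis, elemental modification-mass calculator)
    and an end-to-end experiment harness with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    tiff,
    png
Suggests:
    Matrix,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
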