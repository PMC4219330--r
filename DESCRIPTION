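Package: exposeloc
Title: Protein Subcellular Location Prediction from Exposure-Stratified
    Amino Acid Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the subcellular location of eukaryotic proteins
    (nuclear, nucleocytoplasmic, cytoplasmic, extracellular) from amino
    acid composition stratified by residue solvent exposure. Per-residue
    relative solvent accessibility, either derived from structure (DSSP
    accessibility normalised by per-residue maxima) or predicted from
    sequence (0-9 exposure scores), is binned into six exposure ranges;
    range-restricted 20- and 40-component composition vectors feed
    one-vs-rest probabilistic support vector machines whose class scores
    are stacked by a small feed-forward neural network. Includes dataset
    curation filters, balanced negative sampling, ROC and paralog-pair
    evaluation with a Monte Carlo null, and a synthetic corpus generator
    with class-specific exposure-dependent residue distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
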