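Package: mpminer
Title: Mining, Curation and Consensus QSPR Modeling of Melting-Point Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting melting- and decomposition-point
    declarations from experimental text with a formal-grammar parser,
    normalizing and repairing the recovered temperature intervals,
    associating them with annotated chemical entities, and curating the
    resulting structure-property records (suspicious-value flagging,
    mixture exclusion, duplicate elimination, representative selection).
    Includes estimation of the experimental reproducibility of repeated
    measurements, sparse SMILES-substring (QNPR) descriptors with
    unsupervised filtering, fivefold cross-validated kernel regression
    with consensus averaging and a distance-to-model, Gaussian-null
    outlier filtering with signal-to-noise accounting, a stratified
    bagging classifier for decomposing compounds, hypergeometric
    feature enrichment, the general solubility equation, and synthetic
    corpus and dataset generators with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    e1071,
    rpart,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
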