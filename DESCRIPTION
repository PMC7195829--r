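Package: ecmscout
Title: Sequence-Based Prediction of Extracellular Matrix Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts extracellular matrix (ECM) proteins from sequence-derived
    hybrid features: binary flags for 63 ECM-associated structural domains,
    mean values of 24 physicochemical amino-acid indices, and an 80-dimensional
    descriptor of the position-specific scoring matrix (PSSM) built from
    standardized column means and second-order grey-model GM(2,1) coefficients.
    Features are ranked by maximum-relevance minimum-redundancy (mRMR) with
    incremental feature selection, and classification uses an under-sampling
    ensemble of random forests whose averaged probabilities are evaluated by
    balanced accuracy under stratified 10-fold cross-validation. Includes a
    synthetic-data generator emulating class-informative domains, residue
    composition and PSSM conservation so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    MASS,
    jsonlite,
    optparse,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
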