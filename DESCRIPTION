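Package: dbpred
Title: Sequence- and Profile-Based Prediction of DNA-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for predicting DNA-binding proteins from primary
    sequence and evolutionary profiles. Implements three feature
    encoders: normalized Moreau-Broto autocorrelation over six
    physicochemical properties plus amino-acid composition (200
    features), two-dimensional discrete cosine compression of
    position-specific scoring matrices (100 features), and per-column
    four-level discrete wavelet summaries of the same profiles (1040
    features). Features are ranked by support-vector recursive feature
    elimination with correlation-bias reduction, and classified with a
    radial-basis-function support vector machine evaluated by jackknife
    or k-fold cross-validation with accuracy, sensitivity, specificity,
    Matthews correlation and ROC/AUROC. A synthetic-data module
    generates sequences and profile matrices with controllable class
    signal so the full pipeline is testable without external searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
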