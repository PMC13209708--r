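Package: bcheqsar
Title: QSAR Models of Butyrylcholinesterase Inhibition by Organic Sunscreens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Predicts butyrylcholinesterase (BChE) inhibition potency (pIC50)
    of organic UV filters from six ADMET-type molecular descriptors (nRot,
    Flex, Fsp3, logD, caco2, PPB). Implements the full modeling workflow:
    descriptor correlation and collinearity-tolerance screening, best-subset
    multiple linear regression with leave-one-out Q2 validation, multilayer
    perceptron regression with automated architecture search and global
    sensitivity analysis, epsilon-insensitive support vector regression with
    kernel selection, a PCA confidence-ellipse applicability domain, and
    Morgan-fingerprint PLS atomic-contribution maps. Includes a synthetic
    reference-inhibitor generator that reproduces the published descriptor
    correlation structure so every stage is testable without the external
    literature IC50 compilation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    mixOmics,
    ChemmineR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
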