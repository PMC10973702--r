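Package: sulcalclass
Title: Small-Sample Case-Control Classification of Sulcal Morphometry with
    Analytic Upper-Bound Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for case-control studies of cortical sulcal
    morphometry (length, mean depth, maximum depth per labelled region) in the
    small-sample, high-dimensional regime typical of clinical neuroimaging.
    Provides a seeded synthetic-data generator emulating the statistical
    structure of sulcal feature tables; exclusion-rule preprocessing;
    parametric (Shapiro-Wilk routed t / Mann-Whitney) and classifier-based
    proportion-test feature selection; partial least squares feature
    extraction; linear support vector machine and multilayer perceptron
    classifiers; validation by stratified k-fold cross-validation and by
    resubstitution with upper-bound correction under a concentration
    inequality for linear classifiers and a PAC-Bayes dropout bound; and
    model-agnostic explanation operators (local sparse surrogates, exact and
    kernel-estimated Shapley values).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
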