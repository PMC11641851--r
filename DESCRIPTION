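Package: wavetex
Title: Wavelet Texture Analysis of Grayscale Tumor Images for
    Treatment-Response Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multilevel two-dimensional discrete wavelet decomposition of
    grayscale tumor regions of interest with ten mother wavelets (Haar and
    higher-order Daubechies, Coiflets, Symlets, and biorthogonal splines),
    summarised into 120 named texture features (four coefficient statistics
    at three dyadic levels per wavelet).  Downstream statistics cover
    univariate screening (Lilliefors normality, Welch and pooled two-sample
    t-tests, including a summary-statistics form), forward-stepwise Fisher
    linear discriminant analysis with a Wilks' lambda criterion, a
    discriminant score with ROC/Youden optimal-cutoff selection, confusion
    metrics, and leave-one-out cross-validation.  A seeded generator of
    two-class tumor-like textured image cohorts supports end-to-end testing
    at study-scale cohort sizes, and a pre-fitted reference discriminant
    model for pathological-complete-response prediction ships as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
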