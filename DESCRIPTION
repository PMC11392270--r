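Package: ehgrisk
Title: Preterm-Birth Risk Prediction from the Electrohysterogram
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-invasive prediction of premature birth from
    multi-channel electrohysterogram (EHG) recordings. Implements band-limited
    spectral features (peak frequency, median frequency, normalized
    peak amplitude) and sample entropy over the ten canonical EHG frequency
    bands, sequential forward feature selection stabilized by frequency-based
    aggregation of selected features, leak-free imbalanced-class evaluation
    under the Partition-Synthesis discipline (SMOTE strictly after
    partitioning), averaged ROC curves and decision boundaries, a two-feature
    linear composite biomarker, and a synthetic EHG generator with planted
    class effects so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    e1071
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
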