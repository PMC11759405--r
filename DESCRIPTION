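Package: narxaffect
Title: Dynamic Emotion-Intensity Estimation from Physiological Signals with
    NARX Wavelet-Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for continuous emotion-intensity estimation
    from galvanic skin response, pulse and respiration recordings.  Generates
    protocol-faithful synthetic study data, extracts 13 continuous
    physiological features, fits per-quality nonlinear autoregressive
    exogenous (NARX) models with a wavelet-network output map whose integer
    lag structure is found by exhaustive or genetic-algorithm search under
    sequential forward feature selection, and evaluates intra- and
    intersubject performance against a sliding-window linear-regression
    baseline, with feature ranking, median/MAD summaries, paired Wilcoxon
    comparison and Apriori frequent-itemset mining.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
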