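Package: fuzzybox
Title: Hybrid Propagation of Variability and Fuzzy Uncertainty with
    Probability Boxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint propagation of aleatory variability (Monte Carlo over
    probability distributions) and epistemic uncertainty (generalized fuzzy
    numbers and normal interval-valued fuzzy numbers, via alpha-cut corner
    evaluation) through arbitrary risk models. Produces families of empirical
    CDFs indexed by membership level, probability boxes with interval-valued
    range, mean and variance summaries, and fractile membership functions of
    the model output. Ships the arsenic fish-ingestion non-cancer risk model
    as a worked example, a structured config-file front end, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
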