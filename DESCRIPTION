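Package: pvahmm
Title: Poisson Hidden Markov Models for Patient-Ventilator Asynchrony Count Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling windowed counts of patient-ventilator
    asynchrony events with Poisson hidden Markov models. Provides indexing of
    breath-level asynchrony records into count time series, maximum-likelihood
    fitting by the EM (Baum-Welch) algorithm, Viterbi state decoding,
    equal-tailed Poisson credible intervals, one-step-ahead count forecasting,
    conversion of per-state expected counts into asynchrony rates via a
    Poisson regression with exposure offset, cross-validated forecast
    evaluation against a zero-count base model, state-matched cardiovascular
    episode statistics, and a synthetic-data generator with known ground
    truth for end-to-end testing.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
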