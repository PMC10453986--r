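Package: simonlca
Title: Distributional Analysis of Simon-Task Congruency Effects with a
    Leaky Competing Accumulator Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for distributional analysis of speed-accuracy
    instruction effects on spatial (Simon) congruency at multiple
    feature-onset asynchronies: outlier filtering, per-cell quantile
    summaries, delta plots, overlap-range slopes, third-order polynomial
    level matching at the centre of the speed/accuracy reaction-time
    overlap, binned error-rate congruency effects, repeated-measures
    ANOVA with Greenhouse-Geisser correction and partial eta squared,
    Friedman and Wilcoxon tests, and Cousineau-Morey within-participant
    standard errors. Includes an extended leaky, competing accumulator
    simulator with staggered route onsets and an exponentially decaying
    irrelevant drive, quantile-based chi-square model fitting with
    common random numbers, and parameter-recovery utilities.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
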