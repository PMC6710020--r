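Package: coevonet
Title: Co-Evolution of Friendship Networks and Adolescent Drinking Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic actor-oriented models (SAOMs) for the joint dynamics of
    directed friendship networks and ordinal health behaviors (drinking
    frequency, parental control, adolescent secrecy) observed in multi-wave
    school cohorts. Provides panel ingestion and recoding for roster-style
    friendship nominations, a continuous-time microstep simulator,
    unconditional method-of-moments estimation via Robbins-Monro stochastic
    approximation with convergence diagnostics, goodness-of-fit via degree
    distributions and the directed triad census, empirical-Bayes
    (Paule-Mandel) random-effects meta-analysis and meta-regression on school
    context, pooled ego-alter selection tables with asymmetry contrasts, and a
    synthetic multi-school study generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    igraph,
    withr
Config/testthat/edition: 3
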