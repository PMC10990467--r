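Package: verbalagg
Title: Lexicon-Based Classification of Workplace Verbal Aggression and
    Mental-Health Effect Estimation
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing free-text reports of workplace verbal
    aggression in two-wave occupational cohorts. Classifies utterances into
    aggression categories (criticism of job performance, attacks on
    personality and looks, threats on life, residual other) with a
    configurable lexicon and pluggable tokenizer; scores the CES-D
    depression scale and the Pittsburgh Sleep Quality Index with standard
    caseness cutoffs; estimates crude odds ratios with Woolf confidence
    intervals from 2x2 contingency tables and covariate-adjusted odds
    ratios via maximum-likelihood logistic regression (iteratively
    reweighted least squares, implemented in the package); builds
    conjugation-grouped word-frequency tables for word-cloud rendering;
    and simulates two-wave cohorts with attrition, multi-label exposure
    types and logistic outcomes so that every pipeline stage is testable
    without external data. A command-line interface orchestrates
    simulation, classification, estimation and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
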