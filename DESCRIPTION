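Package: metabf
Title: Frequentist and Bayesian Model-Averaged Meta-Analysis of Binary-Outcome Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools log odds ratios from sets of randomized trials with both
    conventional (fixed-effect and random-effects inverse-variance) and
    Bayesian model-averaged meta-analysis. The Bayesian engine computes
    marginal likelihoods of four models (fixed/random crossed with null/
    alternative) by deterministic quadrature under a Cauchy prior on the
    pooled log odds ratio and an inverse-gamma prior on the between-study
    standard deviation, yielding model-averaged Bayes factors, equal-tailed
    credible intervals, and per-study shrinkage estimates. Includes
    sequential (cumulative) updating in publication order, a synthetic-trial
    generator for operating-characteristic experiments, and plot-ready
    forest and trajectory exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    metafor,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
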