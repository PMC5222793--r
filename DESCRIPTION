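Package: csfbayes
Title: Two-Dimensional Bayesian Estimation of the Contrast Sensitivity
    Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the spatial contrast sensitivity function
    (CSF) from two-alternative forced-choice trial data by gridded Bayesian
    inference over a five-parameter psychometric model (a double-exponential
    CSF carrying a logistic function of log contrast), together with four
    adaptive stimulus-sampling strategies (weighted up-down staircase, the
    per-frequency Psi method, qCSF-style expected-entropy minimization over
    the joint frequency-contrast space, and D-optimal Fisher-information
    selection), a simulated Bernoulli observer, and a Monte-Carlo harness
    reporting pooled RMSE and bias of the estimated CSF in sensitivity
    decibels. Inference is decoupled from sampling, so trial logs collected
    with any procedure can be re-analysed with the same posterior machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
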