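Package: beePER
Title: Automated Scoring and Analysis of Honeybee Proboscis Extension
    Response Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for fully automated analysis of proboscis extension
    response (PER) conditioning experiments in honeybees. Includes
    construction and validation of differential-conditioning protocols
    (balanced CS+/CS- trial sequences, CS/US timing windows, rotor
    inter-trial-interval arithmetic), a synthetic-data module that renders
    labelled 100x100 head-on frames and simulates whole multi-subject
    experiments with known ground truth, a small convolutional network that
    assigns each frame a probability that the proboscis is extended,
    threshold-based trial scoring (learning criterion, pre-CS exclusion,
    innate-PER filter, response latency, area under the probability curve
    per time), learning-curve construction, and mixed-design
    repeated-measures ANOVA with Benjamini-Hochberg corrected per-trial
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
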