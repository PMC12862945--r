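Package: storystates
Title: Context-Modulated Brain-State Dynamics During Naturalistic Story Listening
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Estimates recurring brain states from network-level fMRI time
    series recorded during naturalistic story listening and asks how a prior
    narrative context modulates their dynamics.  Provides Gaussian-emission
    hidden Markov models with dwell-time-informed initialization, restart
    selection and leave-one-subject-out cross-validation; reliability
    screening of state activation patterns (activation, bootstrap
    confidence-interval width, split-half correlation); Jaccard-distance
    consensus clustering of states pooled across groups and model sizes;
    maximum a posteriori Bayesian logistic mixed models linking per-TR story
    annotations to state occupancy and to behavioral button presses, with
    posterior direction probabilities and a Bayesian false discovery rate;
    permutation tests of group time-course differences; and a synthetic-data
    generator that reproduces the statistical structure the analysis assumes
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
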