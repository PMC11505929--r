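Package: solutemap
Title: Bayesian Stochastic Mapping of Habitat Preference and
    Biosynthetic-Pathway Characters on Dated Phylogenies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian inference of discrete-trait evolution on samples
    of dated phylogenies. Fits continuous-time Markov models (unidirectional,
    equal-rates, symmetric, all-rates-different, and dependent multi-gene
    "supercharacter" models) with empirical-Bayes priors, compares them by
    stepping-stone marginal likelihoods, and blends them by Bayesian model
    averaging. Samples full character histories (stochastic mapping) with
    endpoint-conditioned path sampling by uniformization, overlays a
    conditioned focal character driven by a conditional probability table,
    tests character correlation with the D-test, and post-processes history
    collections into node and branch-time posteriors, first-occurrence ages,
    transition rates through time, and loss/gain rate ratios. Includes a
    synthetic-data generator producing dated tree samples and character data
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
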