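Package: ploidyml
Title: Classification and Genetic-Algorithm Optimization of In Vitro
    Tetraploid Induction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models ploidy outcomes (diploid, mixoploid, tetraploid) of in
    vitro antimitotic treatments as a function of oryzalin concentration and
    exposure time. Provides a calibrated dose-response simulator for the
    26-treatment experimental design, from-scratch probabilistic neural
    network (Parzen-kernel), RBF support-vector and cosine-distance
    k-nearest-neighbour classifiers with leave-one-out hyperparameter
    selection, macro-averaged multiclass evaluation metrics, and a
    real-coded genetic algorithm (stochastic universal sampling, scattered
    crossover, adaptive feasible mutation, elitism) that maximizes the
    classifier's tetraploid posterior over the treatment rectangle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
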