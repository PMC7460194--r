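Package: stvcareal
Title: Bayesian Spatiotemporally Varying Coefficient Models for Areal Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation, covariate screening, fitting and comparison of Bayesian
    hierarchical regression models with spatiotemporally varying coefficients
    (STVC) for areal space-time panels such as county-by-year healthcare
    resource counts. Spatially varying coefficients follow an intrinsic
    conditional autoregressive (Besag) prior on the areal adjacency graph and
    temporally varying coefficients follow a first-order random-walk prior;
    inference is by blocked Gibbs sampling on the sparse Gaussian Markov random
    field full conditionals of the log-Gaussian likelihood. Includes iterative
    variance-inflation-factor filtering and random-forest importance screening,
    DIC/WAIC/CPO/R-squared model comparison, Getis-Ord hot-spot classification
    of coefficient surfaces, and a synthetic panel generator with recorded
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
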