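Package: ssinfer
Title: Sparse Inference of S-System Models from Time-Course Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the topology and parameters of S-System (power-law) models
    of biochemical networks from time-course concentration data. The ODE system
    is decoupled equation by equation via five-point slope estimation, and each
    equation is fitted by a mixed-variable multiobjective evolutionary algorithm
    that minimises the slope-fitting error together with the number of network
    connections (an exact L0 norm encoded by binary connection indicators).
    A knee-point based selection procedure automatically picks one network from
    the per-equation nondominated fronts without any user-set pruning threshold.
    Includes the two standard benchmark systems (a five-gene artificial network
    and the yeast fermentation pathway), a seeded synthetic data generator with
    multiplicative noise, and ROC-based topology scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
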