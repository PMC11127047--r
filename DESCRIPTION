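Package: actnem
Title: Simulation and Control of Topological Defects in Active Nematic Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pseudospectral simulation of two-dimensional active nematic
    hydrodynamics (Q-tensor nematodynamics with substrate friction) driven by
    arbitrary space-time activity patterns, together with a design toolkit for
    steering +1/2 and -1/2 disclinations: symmetry-selected activity patterns
    (tweezers, harmonic discs, strips, nucleation patches), winding-number
    defect detection with polarity and triatic orientation extraction,
    trajectory linking and braid analysis, and a coarse-grained one-dimensional
    defect-gas hydrodynamics solver for collective charge patterning in
    activity gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
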