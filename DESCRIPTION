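Package: lstgi
Title: Lifespan-Based Modeling of Tumor Growth Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Delay-differential-equation models of xenograft tumor growth in
    which tumor cells divide at the end of a fixed lifespan with a
    size-dependent division efficiency, together with perturbed variants for
    non-cycle-specific and cycle-specific anticancer drug effects, closed-form
    compartmental pharmacokinetic drivers, a linearized transit-compartment
    reference model, a grid-search plus nonlinear-regression estimation
    workflow, and a synthetic xenograft study generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
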