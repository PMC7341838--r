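Package: axonwalk
Title: Monte-Carlo Diffusion Simulation and Time-Dependence Analysis in
    Beaded Axon Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates synthetic three-dimensional intra-axonal substrates
    with caliber variation (beading), undulation and mitochondria; runs
    continuous-space Monte-Carlo random-walk diffusion simulations with
    compartment-specific diffusivities, membrane permeation and T2
    weighting; reduces walker displacement moments to time-dependent
    diffusivity D(t) and kurtosis K(t) along arbitrary directions; and fits
    the short-range-disorder power law D(t) ~ D_inf + c/sqrt(t) together
    with the one-dimensional structural power spectrum of caliber
    variations. Includes Watson orientation-dispersion sampling, ensemble
    cumulant averaging, dMRI signal synthesis with weighted linear
    least-squares kurtosis fitting, and the statistical tests used to
    assess diffusivity time dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
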