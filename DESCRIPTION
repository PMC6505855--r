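Package: sirews
Title: Critical Slowing Down and Early-Warning Signals for Epidemic
    Transitions in the Stochastic SIR Model with Vaccination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the approach to the immunization threshold
    in a birth-death SIR model with vaccination at birth and low-rate case
    importation ("sparking").  Provides the deterministic skeleton
    (equilibria, Jacobians, eigenvalues, damping ratio, potential wells,
    inter-epidemic period), the linear-noise description of demographic
    fluctuations (diffusion matrix, stationary covariance from the Lyapunov
    equation, generalized variance, 95% concentration ellipses, lagged
    autocovariance), exact event-driven and diffusion-approximation
    simulators with time-varying vaccine-uptake schedules, and estimators of
    early-warning indicators (rolling variance, generalized variance, lag
    autocorrelation, damped-oscillation fits of the ACF, amplitude recovery
    rate, and inversion of the eigenvalue modulus to a distance from the
    threshold).  All user-facing functions take and return tidy data frames.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    deSolve,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
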