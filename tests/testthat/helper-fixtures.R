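# Shared fixture builders: the measles-like example system used throughout.
fig_params <- function(nu = 0, eta = 2e-5) {
  sir_params(R0 = 17, b = 2e5, mu = 0.02, gamma = 365 / 22, eta = eta, nu = nu)
}

# reduced-population variant (N = 1e5) for fast stochastic runs
small_params <- function(nu = 0, eta = 2e-5) {
  sir_params(R0 = 17, b = 2e3, mu = 0.02, gamma = 365 / 22, eta = eta, nu = nu)
}

endemic_eq <- function(params) {
  eq <- equilibria(params)
  eq[eq$branch %in% c("endemic", "sparked"), ]
}

# random valid parameter draw with an underdamped endemic equilibrium
random_endemic_params <- function() {
  repeat {
    R0 <- stats::runif(1, 2, 25)
    nu <- stats::runif(1, 0, 0.9)
    if (R0 * (1 - nu) > 1.05) break
  }
  sir_params(
    R0 = R0,
    b = 10^stats::runif(1, 3, 6),
    mu = stats::runif(1, 0.01, 0.05),
    gamma = stats::runif(1, 5, 60),
    eta = 0,
    nu = nu
  )
}
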