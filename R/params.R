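#' Construct an SIR-with-vaccination parameter set
#'
#' Defines one birth-death SIR system with vaccination at birth and low-rate
#' case importation ("sparking").  Time is measured in years and all rates are
#' per year.  The transmission rate is not supplied directly: the basic
#' reproduction number `R0` is the epidemiologically meaningful control, and
#' `beta` is derived from it via `R0 = N * beta / (gamma + mu)` with
#' `N = b / mu` the expected population size.
#'
#' @param R0 Basic reproduction number (dimensionless, > 0).
#' @param b Birth rate (individuals / year, > 0).
#' @param mu Per-capita death rate (1 / year, > 0).
#' @param gamma Recovery rate (1 / year, > 0).  `1 / gamma` is the mean
#'   infectious period in years.
#' @param eta Per-capita sparking rate (1 / year, >= 0): the rate at which a
#'   susceptible acquires infection from outside the population.
#' @param nu Vaccine uptake, the proportion of births immunized (in `[0, 1]`).
#'
#' @return A one-row tibble of class `sir_params` with columns `b`, `mu`,
#'   `gamma`, `eta`, `nu`, `R0` and the derived `N = b/mu` and
#'   `beta = R0 (gamma + mu) / N`.
#'
#' @details The defaults are the measles-like configuration used throughout
#'   the package's examples: a population of ten million (`b = 2e5`,
#'   `mu = 0.02`), a 22-day infectious period (`gamma = 365/22`), `R0 = 17`
#'   and a small sparking rate `eta = 2e-5`.
#'
#' @examples
#' p <- sir_params()
#' threshold_uptake(p)
#' @export
sir_params <- function(R0 = 17, b = 2e5, mu = 0.02, gamma = 365 / 22,
                       eta = 2e-5, nu = 0) {
  stopifnot(
    "b must be a positive scalar" = is.numeric(b) && length(b) == 1 && b > 0,
    "mu must be a positive scalar" = is.numeric(mu) && length(mu) == 1 && mu > 0,
    "gamma must be a positive scalar" =
      is.numeric(gamma) && length(gamma) == 1 && gamma > 0,
    "eta must be a nonnegative scalar" =
      is.numeric(eta) && length(eta) == 1 && eta >= 0,
    "R0 must be a positive scalar" = is.numeric(R0) && length(R0) == 1 && R0 > 0,
    "nu must lie in [0, 1]" =
      is.numeric(nu) && length(nu) == 1 && nu >= 0 && nu <= 1
  )
  N <- b / mu
  out <- tibble::tibble(
    b = b, mu = mu, gamma = gamma, eta = eta, nu = nu, R0 = R0,
    N = N, beta = R0 * (gamma + mu) / N
  )
  class(out) <- c("sir_params", class(out))
  out
}

#' @export
#' @method print sir_params
print.sir_params <- function(x, ...) {
  cat("<sir_params>  SIR model with vaccination at birth\n")
  cat(sprintf("  R0 = %g, nu = %g  (threshold uptake nu_c = %.4g)\n",
              x$R0, x$nu, threshold_uptake(x)))
  cat(sprintf("  b = %g /y, mu = %g /y, gamma = %g /y, eta = %g /y\n",
              x$b, x$mu, x$gamma, x$eta))
  cat(sprintf("  derived: N = %g, beta = %g /y\n", x$N, x$beta))
  invisible(x)
}

#' Modify the vaccine uptake of a parameter set
#'
#' @param params A [sir_params()] tibble.
#' @param nu New uptake value in `[0, 1]`.
#' @return The parameter set with `nu` replaced (derived fields unchanged:
#'   `beta` does not depend on `nu`).
#' @export
set_uptake <- function(params, nu) {
  stopifnot(inherits(params, "sir_params"),
            is.numeric(nu), length(nu) == 1, nu >= 0, nu <= 1)
  params$nu <- nu
  params
}

#' Critical vaccine uptake (immunization threshold)
#'
#' The controlling parameter of the model is the product `R0 (1 - nu)`; the
#' transcritical bifurcation between the disease-free and endemic regimes sits
#' where it equals one, i.e. at `nu_c = 1 - 1/R0`.
#'
#' @param params A [sir_params()] tibble (only `R0` is used).
#' @return The critical uptake as a plain number.  Negative when `R0 < 1`,
#'   in which case no vaccination is needed to prevent sustained transmission
#'   (a message is emitted).
#' @examples
#' threshold_uptake(sir_params(R0 = 17)) # ~0.941
#' @export
threshold_uptake <- function(params) {
  stopifnot(inherits(params, "sir_params"))
  nu_c <- 1 - 1 / params$R0
  if (nu_c < 0) {
    message("R0 < 1: transmission is not sustained even without vaccination")
  }
  nu_c
}

#' @rdname sir_params
#' @param x A `sir_params` object.
#' @param ... Unused.
#' @export
tidy.sir_params <- function(x, ...) {
  tibble::tibble(
    term = c("b", "mu", "gamma", "eta", "nu", "R0", "N", "beta"),
    value = c(x$b, x$mu, x$gamma, x$eta, x$nu, x$R0, x$N, x$beta),
    units = c("ind/y", "1/y", "1/y", "1/y", "1", "1", "ind", "1/(ind y)")
  )
}
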