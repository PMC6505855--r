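#' Jacobian of the SIR drift at a state
#'
#' Linearization of the deterministic drift about a point `(S, I)`:
#' \deqn{J = \begin{pmatrix} -\beta I - \eta - \mu & -\beta S \\
#'                            \beta I + \eta & \beta S - (\gamma + \mu)
#'           \end{pmatrix}}
#'
#' @param params A [sir_params()] tibble.
#' @param S,I State at which to evaluate (defaults: the system's default
#'   equilibrium, see [equilibria()]).
#' @return A 2x2 numeric matrix with dimnames `c("S", "I")`.
#' @export
jacobian <- function(params, S = NULL, I = NULL) {
  stopifnot(inherits(params, "sir_params"))
  if (is.null(S) || is.null(I)) {
    eq <- default_equilibrium(params)
    S <- eq$S
    I <- eq$I
  }
  p <- params
  J <- matrix(
    c(-p$beta * I - p$eta - p$mu, -p$beta * S,
      p$beta * I + p$eta,          p$beta * S - (p$gamma + p$mu)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("S", "I"), c("S", "I"))
  )
  J
}

#' Local linear stability analysis at an equilibrium
#'
#' Computes the Jacobian at the chosen equilibrium and summarizes its
#' spectrum in the damped-harmonic-oscillator frame: writing the deviation of
#' `I` as `z_I'' - tau z_I' + Delta z_I = 0`, with `tau` the trace and
#' `Delta` the determinant of the Jacobian, perturbations behave like a mass
#' on a spring with damping ratio `zeta = -tau / sqrt(4 Delta)`.  A damping
#' ratio below one means perturbations return through damped oscillations
#' (underdamped); the eigenvalues then form a complex pair whose modulus is
#' `sqrt(Delta)` and whose imaginary part sets the oscillation period
#' `2 pi / Im(lambda)`.
#'
#' @param params A [sir_params()] tibble.
#' @param branch Which equilibrium to analyse: `"auto"` (sparked when
#'   `eta > 0`, else endemic when it exists, else disease-free) or an explicit
#'   branch name.
#' @return An object of class `sir_stability`: a list with the equilibrium
#'   (`branch`, `S`, `I`), the Jacobian `J`, `eigenvalues` (complex pair),
#'   `tau` (1/y), `Delta` (1/y^2), `zeta` (dimensionless; `NaN` when
#'   `Delta <= 0`), `modulus` (1/y, for a complex pair), `period` (years;
#'   `NA` unless underdamped) and `regime` (e.g. `"stable underdamped"`).
#'   Use [tidy()] / [glance()] for tabular forms.
#'
#' @examples
#' st <- stability(sir_params(nu = 0, eta = 0))
#' glance(st)
#' @export
stability <- function(params, branch = "auto") {
  stopifnot(inherits(params, "sir_params"))
  eq <- default_equilibrium(params, branch)
  J <- jacobian(params, S = eq$S, I = eq$I)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev), -Im(ev))]
  tau <- sum(diag(J))
  Delta <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  underdamped <- any(abs(Im(ev)) > 0)
  zeta <- if (Delta > 0) -tau / sqrt(4 * Delta) else NaN
  modulus <- if (underdamped) Mod(ev[1]) else NA_real_
  period <- if (underdamped) 2 * pi / abs(Im(ev[1])) else NA_real_
  stab <- if (all(Re(ev) < 0)) "stable" else "unstable"
  damp <- if (underdamped) {
    "underdamped"
  } else if (is.nan(zeta)) {
    "non-oscillatory"
  } else if (abs(zeta - 1) < 1e-10) {
    "critical"
  } else {
    "overdamped"
  }
  structure(
    list(
      branch = eq$branch, S = eq$S, I = eq$I,
      J = J, eigenvalues = ev,
      tau = tau, Delta = Delta, zeta = zeta,
      modulus = modulus, period = period,
      regime = paste(stab, damp),
      params = params
    ),
    class = "sir_stability"
  )
}

#' @export
#' @method print sir_stability
print.sir_stability <- function(x, ...) {
  cat("<sir_stability> ", x$branch, " equilibrium at (S, I) = (",
      format(x$S, digits = 7), ", ", format(x$I, digits = 7), ")\n", sep = "")
  cat("  eigenvalues:", format(x$eigenvalues, digits = 6), "per year\n")
  cat(sprintf("  tau = %.6g /y, Delta = %.6g /y^2, zeta = %.6g\n",
              x$tau, x$Delta, x$zeta))
  if (!is.na(x$period)) {
    cat(sprintf("  oscillation period = %.4f y, modulus = %.6g /y\n",
                x$period, x$modulus))
  }
  cat("  regime:", x$regime, "\n")
  invisible(x)
}

#' Tidy a stability report
#'
#' @param x A `sir_stability` object.
#' @param ... Unused.
#' @return `tidy()` gives one row per eigenvalue (`eigenvalue`, `real`,
#'   `imaginary`, `modulus`); `glance()` gives a one-row summary (`branch`,
#'   `S`, `I`, `tau`, `Delta`, `zeta`, `modulus`, `period`, `regime`).
#' @export
tidy.sir_stability <- function(x, ...) {
  tibble::tibble(
    eigenvalue = seq_along(x$eigenvalues),
    real = Re(x$eigenvalues),
    imaginary = Im(x$eigenvalues),
    modulus = Mod(x$eigenvalues)
  )
}

#' @rdname tidy.sir_stability
#' @export
glance.sir_stability <- function(x, ...) {
  tibble::tibble(
    branch = x$branch, S = x$S, I = x$I,
    tau = x$tau, Delta = x$Delta, zeta = x$zeta,
    modulus = x$modulus, period = x$period, regime = x$regime
  )
}

#' Closed-form eigenvalue approximations near the endemic equilibrium
#'
#' For a long-lived host (`mu << gamma`) well inside the endemic regime
#' (`R0 (1 - nu) >> 1`), the endemic eigenvalues are approximately
#' `-mu R0 (1 - nu) / 2 +- i sqrt(mu (R0 (1 - nu) - 1) gamma)`.
#'
#' @param params A [sir_params()] tibble with `R0 (1 - nu) > 1`.
#' @return A one-row tibble with `re_approx` and `im_approx` (1/y).
#' @export
eigenvalue_approximations <- function(params) {
  stopifnot(inherits(params, "sir_params"))
  x <- params$R0 * (1 - params$nu)
  if (x <= 1) {
    stop("R0 (1 - nu) must exceed 1: no endemic oscillations to approximate",
         call. = FALSE)
  }
  tibble::tibble(
    re_approx = -params$mu * x / 2,
    im_approx = sqrt(params$mu * (x - 1) * params$gamma)
  )
}

#' Inter-epidemic period prediction
#'
#' The classic period formula `2 pi sqrt(A D)`, with `A` the mean age at
#' infection (approximately `1 / [mu (R0 (1 - nu) - 1)]` for small `mu`) and
#' `D = 1 / gamma` the mean infectious period, recovered from the imaginary
#' part of the endemic eigenvalues.  The exact period `2 pi / Im(lambda)`
#' from the full Jacobian (at `eta = 0`) is reported alongside.
#'
#' @param params A [sir_params()] tibble with `R0 (1 - nu) > 1`.
#' @return A one-row tibble with `A` (years), `D` (years), `period_approx`
#'   and `period_exact` (years; `period_exact` is `NA` when the endemic point
#'   is not underdamped).
#' @examples
#' period_prediction(sir_params(nu = 0, eta = 0))
#' @export
period_prediction <- function(params) {
  stopifnot(inherits(params, "sir_params"))
  x <- params$R0 * (1 - params$nu)
  if (x <= 1) {
    stop("at or above the immunization threshold: no endemic period",
         call. = FALSE)
  }
  A <- 1 / (params$mu * (x - 1))
  D <- 1 / params$gamma
  p0 <- set_uptake(params, params$nu)
  p0$eta <- 0
  st <- stability(p0, branch = "endemic")
  tibble::tibble(
    A = A, D = D,
    period_approx = 2 * pi * sqrt(A * D),
    period_exact = st$period
  )
}

#' Potential well of the linearized infected deviation
#'
#' Integrating the restoring force of the damped-oscillator form of the
#' linearized dynamics gives the potential `V(z_I) = Delta z_I^2 / 2`; the
#' well gets shallower as the determinant `Delta` of the Jacobian shrinks on
#' the approach to the immunization threshold.
#'
#' @param Delta Determinant of the Jacobian (1/y^2), e.g. from [stability()].
#' @param z_I Deviation(s) of `I` from equilibrium (individuals, or
#'   prevalence units if rescaled).
#' @param scale Optional multiplicative rescaling of `z_I` before evaluation,
#'   e.g. `sqrt(b/mu)` to express deviations per unit prevalence as in
#'   well-depth displays.
#' @return Numeric vector `Delta * (scale * z_I)^2 / 2`.
#' @export
potential <- function(Delta, z_I, scale = 1) {
  stopifnot(is.numeric(Delta), length(Delta) == 1, is.numeric(z_I))
  Delta * (scale * z_I)^2 / 2
}

#' Uptake at which the endemic dynamics become underdamped
#'
#' Locates the root of `zeta(nu) = 1` on the stable branch below the
#' immunization threshold: above this uptake perturbations of prevalence
#' return through overshooting oscillations rather than monotone decay.
#' The damping ratio is evaluated at the system's equilibrium for its actual
#' sparking rate `eta` (pass `eta = 0` in `params` for the sparking-free
#' variant).
#'
#' @param params A [sir_params()] tibble; its `nu` entry is ignored.
#' @param interval Search bracket for the root; default
#'   `[0.9 * nu_c, nu_c - 1e-6]`.
#' @param tol Absolute tolerance on the root (default `1e-6`).
#' @return The uptake `nu*` at which `zeta = 1`, as a plain number.
#' @examples
#' underdamped_boundary(sir_params()) # ~0.939 for the default parameters
#' @export
underdamped_boundary <- function(params, interval = NULL, tol = 1e-6) {
  stopifnot(inherits(params, "sir_params"))
  nu_c <- threshold_uptake(params)
  if (is.null(interval)) interval <- c(0.9 * nu_c, nu_c - 1e-6)
  f <- function(nu) {
    st <- stability(set_uptake(params, nu))
    st$zeta - 1
  }
  flo <- f(interval[1])
  fhi <- f(interval[2])
  if (is.nan(flo) || is.nan(fhi) || flo * fhi > 0) {
    stop(sprintf(
      "zeta - 1 does not change sign on [%.6g, %.6g] (values %.4g, %.4g)",
      interval[1], interval[2], flo, fhi
    ), call. = FALSE)
  }
  stats::uniroot(f, interval, tol = tol)$root
}

#' Propagate a small deviation under the linearized dynamics
#'
#' Solves `dz/dt = J z` by the matrix exponential, giving the superposition
#' `z(t) = k1 exp(lambda1 t) + k2 exp(lambda2 t)` with coefficients set by
#' the initial deviation.
#'
#' @param J 2x2 Jacobian matrix.
#' @param z0 Initial deviation `(z_S, z_I)`.
#' @param t Nonnegative time(s) in years.
#' @return A tibble with columns `t`, `z_S`, `z_I`.
#' @export
linear_solution <- function(J, z0, t) {
  stopifnot(is.matrix(J), all(dim(J) == c(2, 2)),
            is.numeric(z0), length(z0) == 2,
            is.numeric(t), all(t >= 0))
  z <- vapply(t, function(tt) {
    as.numeric(Matrix::expm(J * tt) %*% z0)
  }, numeric(2))
  tibble::tibble(t = t, z_S = z[1, ], z_I = z[2, ])
}
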