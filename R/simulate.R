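#' Vaccine-uptake schedule
#'
#' Describes how vaccine uptake `nu(t)` changes over a simulation.  Three
#' modes: `constant` (uptake `nu0` throughout), `linear_ramp` (uptake `nu0`
#' until `ramp_start`, then increasing — or decreasing — at `ramp_rate` per
#' year), and `piecewise` (linear interpolation through `breakpoints`, held
#' constant beyond the first/last).  Uptake is always clipped to `[0, 1]`.
#'
#' @param mode One of `"constant"`, `"linear_ramp"`, `"piecewise"`.
#' @param nu0 Starting uptake.
#' @param ramp_rate Uptake change per year (linear_ramp mode).
#' @param ramp_start Year the ramp begins (linear_ramp mode).
#' @param breakpoints Data frame with columns `time`, `nu` (piecewise mode);
#'   times must be strictly increasing.
#' @return A `vaccine_schedule` object.
#' @examples
#' # uptake rising by 0.025/year from zero starting in year 20
#' sch <- vaccine_schedule("linear_ramp", nu0 = 0, ramp_rate = 0.025,
#'                         ramp_start = 20)
#' uptake_at(sch, c(0, 20, 40, 80))
#' @export
vaccine_schedule <- function(mode = c("constant", "linear_ramp", "piecewise"),
                             nu0 = 0, ramp_rate = 0, ramp_start = 0,
                             breakpoints = NULL) {
  mode <- match.arg(mode)
  if (mode == "piecewise") {
    stopifnot(
      "breakpoints must be a data frame with columns time, nu" =
        is.data.frame(breakpoints) &&
          all(c("time", "nu") %in% names(breakpoints)),
      "breakpoint times must be strictly increasing" =
        all(diff(breakpoints$time) > 0)
    )
  }
  structure(
    list(mode = mode, nu0 = nu0, ramp_rate = ramp_rate,
         ramp_start = ramp_start, breakpoints = breakpoints),
    class = "vaccine_schedule"
  )
}

#' @rdname vaccine_schedule
#' @param schedule A `vaccine_schedule`.
#' @param t Time(s) in years.
#' @return `uptake_at()` returns `nu(t)`, clipped to `[0, 1]`.
#' @export
uptake_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "vaccine_schedule"))
  nu <- switch(schedule$mode,
    constant = rep(schedule$nu0, length(t)),
    linear_ramp = schedule$nu0 +
      schedule$ramp_rate * pmax(0, t - schedule$ramp_start),
    piecewise = stats::approx(schedule$breakpoints$time,
                              schedule$breakpoints$nu, xout = t,
                              rule = 2)$y
  )
  pmin(1, pmax(0, nu))
}

#' @export
#' @method print vaccine_schedule
print.vaccine_schedule <- function(x, ...) {
  cat("<vaccine_schedule>", x$mode)
  if (x$mode == "constant") cat(" nu =", x$nu0)
  if (x$mode == "linear_ramp") {
    cat(sprintf(" nu0 = %g, %+g/year from year %g", x$nu0, x$ramp_rate,
                x$ramp_start))
  }
  cat("\n")
  invisible(x)
}

# knots on which the C++ core interpolates nu(t)
schedule_knots <- function(schedule, T) {
  if (is.null(schedule)) schedule <- vaccine_schedule("constant", nu0 = NA)
  switch(schedule$mode,
    constant = list(t = 0, nu = schedule$nu0),
    linear_ramp = {
      tt <- c(0, schedule$ramp_start, T)
      if (schedule$ramp_rate != 0) {
        # knots where the unclipped ramp crosses 0 or 1
        cross <- schedule$ramp_start + (c(0, 1) - schedule$nu0) /
          schedule$ramp_rate
        tt <- c(tt, cross[cross > 0 & cross < T])
      }
      tt <- sort(unique(tt))
      list(t = tt, nu = uptake_at(schedule, tt))
    },
    piecewise = {
      tt <- sort(unique(c(0, schedule$breakpoints$time, T)))
      list(t = tt, nu = uptake_at(schedule, tt))
    }
  )
}

new_timeseries <- function(t, S, I, nu, meta) {
  out <- tibble::tibble(t = t, S = S, I = I, nu = nu)
  attr(out, "meta") <- meta
  class(out) <- c("sir_timeseries", class(out))
  out
}

#' Retrieve simulation metadata
#'
#' @param series A `sir_timeseries` tibble produced by one of the simulators.
#' @return The `meta` list (method, seed, parameters, step sizes).
#' @export
ts_meta <- function(series) attr(series, "meta")

default_init <- function(params, schedule) {
  p <- if (!is.null(schedule)) {
    set_uptake(params, uptake_at(schedule, 0))
  } else {
    params
  }
  eq <- default_equilibrium(p)
  c(S = eq$S, I = eq$I)
}

#' Exact event-driven (Gillespie) simulation
#'
#' Samples the continuous-time Markov chain whose six events are: birth of a
#' susceptible at rate `b (1 - nu(t))`, death of a susceptible at `mu S`,
#' transmission at `beta S I`, sparking at `eta S` (a susceptible infected
#' from outside), recovery at `gamma I`, and death of an infected at `mu I`.
#' Recovery and death of infecteds are separate events; together they give
#' the `(gamma + mu) I` variance term of the diffusion matrix.  The algorithm
#' is exact for constant uptake; for time-varying schedules rates are
#' refreshed at most every `refresh` years (default one day).
#'
#' @param params A [sir_params()] tibble.
#' @param T Horizon in years.
#' @param schedule Optional [vaccine_schedule()]; default constant uptake at
#'   `params$nu`.
#' @param init Named vector `c(S =, I =)` of nonnegative integers; default
#'   the rounded equilibrium for the initial uptake.
#' @param sample_dt Sampling interval in years (default one week).
#' @param seed Integer seed (required; recorded in metadata).
#' @param refresh Maximum time between rate refreshes under a time-varying
#'   schedule (years).
#' @return A `sir_timeseries` tibble `(t, S, I, nu)` with metadata attribute.
#' @examples
#' ts <- gillespie(sir_params(b = 2e3, nu = 0.5), T = 5, seed = 1)
#' @export
gillespie <- function(params, T, schedule = NULL, init = NULL,
                      sample_dt = 1 / 52, seed, refresh = 1 / 365) {
  stopifnot(inherits(params, "sir_params"), T > 0, sample_dt > 0)
  if (missing(seed)) stop("a seed is required for stochastic runs",
                          call. = FALSE)
  if (is.null(init)) init <- round(default_init(params, schedule))
  stopifnot(
    "init must be named nonnegative integers c(S=, I=)" =
      all(c("S", "I") %in% names(init)) && all(init >= 0) &&
        all(init == round(init))
  )
  if (is.null(schedule)) {
    schedule <- vaccine_schedule("constant", nu0 = params$nu)
  }
  kn <- schedule_knots(schedule, T)
  set.seed(seed)
  res <- gillespie_cpp(params$b, params$mu, params$gamma, params$eta,
                       params$beta, init[["S"]], init[["I"]], T, sample_dt,
                       kn$t, kn$nu, refresh)
  new_timeseries(res$t, res$S, res$I, res$nu,
                 meta = list(method = "gillespie", seed = seed,
                             params = params, schedule = schedule,
                             sample_dt = sample_dt, refresh = refresh))
}

#' Euler-Maruyama integration of the diffusion approximation
#'
#' Integrates the stochastic differential equations for `(S, I)` with
#' demographic noise of covariance given by [diffusion_matrix()].  The noise
#' increment at each step is assembled per event channel — an independent
#' normal with variance `rate x dt` times the event's stoichiometry — which
#' is an exact square-root factorization of the diffusion matrix and keeps it
#' positive semidefinite even at the boundary.  States are floored at zero
#' after each step (the standard truncation fix for diffusion approximations
#' of counts).
#'
#' @inheritParams gillespie
#' @param dt Integration step in years (default one day); must be small
#'   against `1 / (gamma + mu)`.
#' @param noise Set `FALSE` for the deterministic drift only (then `seed` is
#'   not needed).
#' @return A `sir_timeseries` tibble sampled at every step.
#' @export
euler_maruyama <- function(params, T, schedule = NULL, dt = 1 / 365,
                           init = NULL, seed = NULL, noise = TRUE) {
  stopifnot(inherits(params, "sir_params"), T > 0, dt > 0)
  if (noise && is.null(seed)) {
    stop("a seed is required for stochastic runs", call. = FALSE)
  }
  if (is.null(init)) init <- default_init(params, schedule)
  if (is.null(schedule)) {
    schedule <- vaccine_schedule("constant", nu0 = params$nu)
  }
  n <- floor(T / dt)
  tt <- (0:n) * dt
  nu_t <- uptake_at(schedule, tt)
  S <- I <- numeric(n + 1)
  S[1] <- init[["S"]]
  I[1] <- init[["I"]]
  if (noise) {
    set.seed(seed)
    Z <- matrix(stats::rnorm(6 * n), nrow = n)
  }
  p <- params
  sq_dt <- sqrt(dt)
  for (k in seq_len(n)) {
    s <- S[k]
    i <- I[k]
    nu <- nu_t[k]
    # event rates: birth, death S, transmission, sparking, recovery, death I
    r <- c(p$b * (1 - nu), p$mu * s, p$beta * s * i, p$eta * s,
           p$gamma * i, p$mu * i)
    dS <- (r[1] - r[2] - r[3] - r[4]) * dt
    dI <- (r[3] + r[4] - r[5] - r[6]) * dt
    if (noise) {
      w <- sqrt(r) * sq_dt * Z[k, ]
      dS <- dS + w[1] - w[2] - w[3] - w[4]
      dI <- dI + w[3] + w[4] - w[5] - w[6]
    }
    S[k + 1] <- max(0, s + dS)
    I[k + 1] <- max(0, i + dI)
  }
  new_timeseries(tt, S, I, nu_t,
                 meta = list(method = "euler_maruyama",
                             seed = if (noise) seed else NA,
                             params = params, schedule = schedule, dt = dt,
                             noise = noise))
}

#' Exact sampling of the linearized (Ornstein-Uhlenbeck) fluctuations
#'
#' Simulates deviations `z = (z_S, z_I)` from the equilibrium under the
#' linear-noise approximation, using the exact discrete-time recursion: the
#' propagator is `exp(J dt)` and the innovation covariance is
#' `Sigma - exp(J dt) Sigma exp(J dt)^T`, so the chain is stationary from the
#' first sample when initialized from the stationary law (the default).
#'
#' @param J Stable 2x2 Jacobian (e.g. `stability(params)$J`).
#' @param B 2x2 diffusion matrix at the equilibrium.
#' @param T Horizon in years.
#' @param dt Sampling interval in years (default one week).
#' @param seed Integer seed.
#' @param init Optional initial deviation `c(S =, I =)`; default a draw from
#'   the stationary distribution.
#' @return A `sir_timeseries` tibble whose `S` and `I` columns hold
#'   *deviations* from equilibrium (`meta$deviations = TRUE`); `nu` is `NA`.
#' @export
ou_sample <- function(J, B, T, dt = 1 / 52, seed, init = NULL) {
  stopifnot(is.matrix(J), all(dim(J) == c(2, 2)), T > 0, dt > 0)
  if (missing(seed)) stop("a seed is required for stochastic runs",
                          call. = FALSE)
  Sigma <- stationary_covariance(J, B)
  F <- as.matrix(Matrix::expm(J * dt))
  Q <- Sigma - F %*% Sigma %*% t(F)
  Q <- (Q + t(Q)) / 2
  eq <- eigen(Q, symmetric = TRUE)
  L <- eq$vectors %*% diag(sqrt(pmax(eq$values, 0)))
  n <- floor(T / dt)
  set.seed(seed)
  Z <- matrix(stats::rnorm(2 * (n + 1)), nrow = 2)
  z <- matrix(0, nrow = 2, ncol = n + 1)
  z[, 1] <- if (is.null(init)) {
    es <- eigen(Sigma, symmetric = TRUE)
    es$vectors %*% (sqrt(pmax(es$values, 0)) * Z[, 1])
  } else {
    c(init[["S"]], init[["I"]])
  }
  for (k in seq_len(n)) {
    z[, k + 1] <- F %*% z[, k] + L %*% Z[, k + 1]
  }
  new_timeseries((0:n) * dt, z[1, ], z[2, ], NA_real_,
                 meta = list(method = "ou", seed = seed, J = J, B = B,
                             Sigma = Sigma, dt = dt, deviations = TRUE))
}

#' Deterministic (noise-free) trajectory
#'
#' Adaptive-step integration of the deterministic drift with an optional
#' uptake schedule, via `deSolve::ode` (lsoda).
#'
#' @inheritParams gillespie
#' @param sample_dt Output sampling interval (years).
#' @return A `sir_timeseries` tibble.
#' @examples
#' p <- sir_params(nu = 0.9, eta = 0)
#' eq <- equilibria(p)
#' ts <- ode_trajectory(p, T = 20,
#'                      init = c(S = eq$S[2] * 1.05, I = eq$I[2] * 1.5))
#' @export
ode_trajectory <- function(params, T, schedule = NULL, init = NULL,
                           sample_dt = 1 / 52) {
  stopifnot(inherits(params, "sir_params"), T > 0)
  if (is.null(init)) init <- default_init(params, schedule)
  if (is.null(schedule)) {
    schedule <- vaccine_schedule("constant", nu0 = params$nu)
  }
  p <- params
  drift <- function(t, y, parms) {
    nu <- uptake_at(schedule, t)
    inf <- p$beta * y[1] * y[2] + p$eta * y[1]
    list(c(
      S = -inf + p$b * (1 - nu) - p$mu * y[1],
      I = inf - (p$gamma + p$mu) * y[2]
    ))
  }
  tt <- seq(0, T, by = sample_dt)
  sol <- deSolve::ode(y = c(S = init[["S"]], I = init[["I"]]), times = tt,
                      func = drift, parms = NULL, rtol = 1e-10, atol = 1e-8)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed (lsoda istate ", attr(sol, "istate")[1],
         ") for T = ", T, call. = FALSE)
  }
  new_timeseries(sol[, "time"], sol[, "S"], sol[, "I"],
                 uptake_at(schedule, sol[, "time"]),
                 meta = list(method = "ode", seed = NA, params = params,
                             schedule = schedule, sample_dt = sample_dt))
}
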