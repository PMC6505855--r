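#' Rolling-window variance indicators
#'
#' Sample second moments of `(S, I)` over sliding windows: per-window
#' deviations are taken about the window mean, and the generalized variance
#' is the determinant of the 2x2 sample covariance.  Rising variance of the
#' monitored series is the classic statistical signature of critical slowing
#' down: perturbations dissipate more slowly near the threshold and
#' variation accumulates.
#'
#' @param series A tibble with columns `t`, `S`, `I` on a regular grid
#'   (any `sir_timeseries`).
#' @param window Window length in years (default 10).
#' @param stride Spacing between window centers in years (default 1).
#' @param detrend How to form within-window deviations: about the window
#'   mean (`"mean"`, the default, matching the near-stationary linearized
#'   theory) or about a within-window linear fit (`"linear"`, appropriate
#'   when a drifting control parameter moves the equilibrium through the
#'   window, as under an uptake ramp).
#' @return An `ews_series` tibble with columns `window_center`, `var_S`,
#'   `var_I`, `cov_SI`, `gen_var`, `n`.
#' @examples
#' p <- sir_params(b = 2e3, nu = 0.5)
#' ts <- gillespie(p, T = 60, seed = 1)
#' windowed_moments(ts)
#' @export
windowed_moments <- function(series, window = 10, stride = 1,
                             detrend = c("mean", "linear")) {
  check_series(series)
  detrend <- match.arg(detrend)
  win <- window_index(series$t, window, stride, min_n = 10)
  rows <- purrr::map(win, function(w) {
    S <- detrend_values(series$S[w$idx], series$t[w$idx], detrend)
    I <- detrend_values(series$I[w$idx], series$t[w$idx], detrend)
    cv <- stats::cov(cbind(S, I))
    tibble::tibble(
      window_center = w$center,
      var_S = cv[1, 1], var_I = cv[2, 2], cov_SI = cv[1, 2],
      gen_var = det(cv), n = length(w$idx)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ews_series", class(out))
  out
}

#' Rolling-window lag autocorrelation
#'
#' Autocorrelation of the within-window deviations of `S` and `I` at a fixed
#' lag.  Near the threshold the dominant eigenvalue approaches zero, so
#' deviations persist longer and the lag autocorrelation of the infected
#' series typically rises.  The lag is interpolated linearly when it is not a
#' multiple of the sampling interval.
#'
#' @inheritParams windowed_moments
#' @param lag Lag in years (default 1); must be below `window / 4`.
#' @return An `ews_series` tibble with columns `window_center`, `acf_S`,
#'   `acf_I`, `lag`, `n`; windows with too few pairs at the lag get `NA` and
#'   `flagged = TRUE`.
#' @export
windowed_acf <- function(series, window = 10, lag = 1, stride = 1,
                         detrend = c("mean", "linear")) {
  check_series(series)
  detrend <- match.arg(detrend)
  stopifnot("lag must be below window/4" = lag < window / 4, lag > 0)
  dt <- median(diff(series$t))
  win <- window_index(series$t, window, stride, min_n = 10)
  rows <- purrr::map(win, function(w) {
    S <- detrend_values(series$S[w$idx], series$t[w$idx], detrend)
    I <- detrend_values(series$I[w$idx], series$t[w$idx], detrend)
    a_S <- acf_at_lag(S, lag, dt)
    a_I <- acf_at_lag(I, lag, dt)
    tibble::tibble(
      window_center = w$center, acf_S = a_S, acf_I = a_I,
      lag = lag, n = length(w$idx),
      flagged = is.na(a_S) || is.na(a_I)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ews_series", class(out))
  out
}

# lag-k sample autocorrelation with linear interpolation between the two
# bracketing integer lags on the sample grid
acf_at_lag <- function(x, lag, dt) {
  k <- lag / dt
  k0 <- floor(k)
  k1 <- ceiling(k)
  r0 <- acf_int(x, k0)
  if (k1 == k0) return(r0)
  r1 <- acf_int(x, k1)
  r0 + (k - k0) * (r1 - r0)
}

acf_int <- function(x, k) {
  n <- length(x)
  if (k >= n - 2 || n < 4) return(NA_real_)
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom == 0) return(NA_real_)
  sum(x[1:(n - k)] * x[(1 + k):n]) / denom
}

#' Empirical autocorrelation curve of a time series
#'
#' Full-series sample ACF of `S` and `I` on the sampling grid, up to a
#' maximum lag — the estimator-side counterpart of [acf_theoretical()], and
#' the natural input to [fit_damped_oscillation()].
#'
#' @inheritParams windowed_moments
#' @param max_lag Largest lag in years.
#' @param demean Subtract the series mean first (default `TRUE`).
#' @return A tibble with columns `lag`, `acf_S`, `acf_I`.
#' @export
acf_curve <- function(series, max_lag = 10, demean = TRUE) {
  check_series(series)
  dt <- median(diff(series$t))
  kmax <- min(floor(max_lag / dt), nrow(series) - 2)
  a_S <- stats::acf(series$S, lag.max = kmax, plot = FALSE,
                    demean = demean)$acf[, 1, 1]
  a_I <- stats::acf(series$I, lag.max = kmax, plot = FALSE,
                    demean = demean)$acf[, 1, 1]
  tibble::tibble(lag = (0:kmax) * dt, acf_S = a_S, acf_I = a_I)
}

#' Fit a damped oscillation to an autocorrelation curve
#'
#' Near an underdamped equilibrium the ACF of the fluctuations decays as a
#' damped cosine; fitting `r(l) = exp(-a l) cos(w l + phi)` estimates the
#' damping rate `a` (the magnitude of the real part of the dominant
#' eigenvalue) and angular frequency `w` (its imaginary part).  The
#' nonlinear least-squares fit is multi-started over phase and frequency,
#' with the frequency initialized from the curve's first zero crossing; ties
#' are broken by lowest residual then lowest frequency.
#'
#' @param acf_values Data frame with columns `lag` and `value` (at least 8
#'   points spanning one oscillation period), e.g. built from [acf_curve()]
#'   or [acf_theoretical()] output.
#' @return An object of class `ews_osc_fit` with elements `damping` (1/y),
#'   `frequency` (1/y), `phase`, `rss`, `overdamped` (`TRUE` when the fitted
#'   frequency is negligible) and the fitted data; `tidy()` gives a one-row
#'   tibble.
#' @examples
#' l <- seq(0, 40, by = 0.5)
#' fit <- fit_damped_oscillation(data.frame(lag = l,
#'                                          value = exp(-0.05 * l) * cos(0.5 * l)))
#' tidy(fit)
#' @export
fit_damped_oscillation <- function(acf_values) {
  stopifnot(is.data.frame(acf_values),
            all(c("lag", "value") %in% names(acf_values)))
  d <- dplyr::arrange(acf_values[stats::complete.cases(acf_values), ], lag)
  if (nrow(d) < 8) stop("need at least 8 lag points", call. = FALSE)

  # frequency guess from the first zero crossing (quarter period)
  sgn <- sign(d$value)
  cross <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  w0 <- if (length(cross) > 0) {
    l0 <- d$lag[cross[1]] +
      (d$lag[cross[1] + 1] - d$lag[cross[1]]) *
        abs(d$value[cross[1]]) /
        (abs(d$value[cross[1]]) + abs(d$value[cross[1] + 1]))
    pi / (2 * l0)
  } else {
    pi / (2 * max(d$lag))
  }
  span <- max(d$lag) - min(d$lag)
  a0 <- 1 / span

  starts <- expand.grid(
    a = a0 * c(0.3, 1, 3),
    w = w0 * c(0.5, 1, 2),
    phi = c(-0.5, 0, 0.5)
  )
  fits <- purrr::pmap(starts, function(a, w, phi) {
    tryCatch(
      minpack.lm::nlsLM(
        value ~ exp(-a * lag) * cos(w * lag + phi),
        data = d, start = list(a = a, w = w, phi = phi),
        lower = c(a = 0, w = 0, phi = -pi), upper = c(Inf, Inf, pi),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    stop("damped-oscillation fit failed to converge from every start ",
         "(", nrow(d), " lag points, span ", signif(span, 3), " y)",
         call. = FALSE)
  }
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  ws <- vapply(fits, function(f) stats::coef(f)[["w"]], numeric(1))
  best <- order(round(rss, 12), ws)[1]
  cf <- stats::coef(fits[[best]])
  structure(
    list(damping = cf[["a"]], frequency = cf[["w"]], phase = cf[["phi"]],
         rss = rss[best], overdamped = cf[["w"]] < 1e-3 / span,
         data = d, fit = fits[[best]]),
    class = "ews_osc_fit"
  )
}

#' @export
#' @method print ews_osc_fit
print.ews_osc_fit <- function(x, ...) {
  cat(sprintf(
    "<ews_osc_fit> damping = %.5g /y, frequency = %.5g /y (period %.3g y)%s\n",
    x$damping, x$frequency,
    if (x$frequency > 0) 2 * pi / x$frequency else Inf,
    if (x$overdamped) " [overdamped: frequency ~ 0]" else ""
  ))
  invisible(x)
}

#' @rdname fit_damped_oscillation
#' @param x An `ews_osc_fit` object.
#' @param ... Unused.
#' @export
tidy.ews_osc_fit <- function(x, ...) {
  tibble::tibble(
    damping = x$damping, frequency = x$frequency, phase = x$phase,
    period = ifelse(x$frequency > 0, 2 * pi / x$frequency, Inf),
    rss = x$rss, overdamped = x$overdamped
  )
}

#' Recovery rate of the oscillation amplitude
#'
#' For a deterministic trajectory relaxing to the endemic equilibrium, the
#' recovery rate is the slope of log amplitude against time,
#' `lambda = d ln r / dt`, with `r` the amplitude of the oscillation of
#' `(I - I*) / N`.  Peaks of `|I - I*| / N` are extracted as discrete local
#' maxima refined by quadratic interpolation (plateaus take the leftmost
#' point) and log amplitude is regressed on peak time.
#'
#' @param series A noise-free `sir_timeseries` (from [ode_trajectory()] or
#'   [euler_maruyama()] with `noise = FALSE`).
#' @param I_star Equilibrium infected count the trajectory relaxes to
#'   (default: the default equilibrium of the series' parameters).
#' @param N Population size used to scale amplitudes (default from the
#'   series' parameters).
#' @return A list of class `ews_recovery` with `lambda_hat` (1/y; negative
#'   for decaying oscillations), `peaks` (tibble of `time`, `amplitude`) and
#'   the regression fit; `tidy()` gives a one-row tibble.
#' @export
recovery_rate <- function(series, I_star = NULL, N = NULL) {
  check_series(series)
  meta <- ts_meta(series)
  if (is.null(I_star) || is.null(N)) {
    if (is.null(meta$params)) {
      stop("supply I_star and N when the series carries no parameters",
           call. = FALSE)
    }
    eq <- default_equilibrium(meta$params)
    if (is.null(I_star)) I_star <- eq$I
    if (is.null(N)) N <- meta$params$N
  }
  amp <- abs(series$I - I_star) / N
  pk <- find_peaks(series$t, amp)
  if (nrow(pk) < 3) {
    stop("need at least 3 oscillation peaks, found ", nrow(pk), call. = FALSE)
  }
  fit <- stats::lm(log(amplitude) ~ time, data = pk)
  structure(
    list(lambda_hat = unname(stats::coef(fit)[2]), peaks = pk, fit = fit),
    class = "ews_recovery"
  )
}

# discrete local maxima with quadratic refinement; leftmost point on plateaus
find_peaks <- function(t, x) {
  n <- length(x)
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (length(i) == 0) {
    return(tibble::tibble(time = numeric(), amplitude = numeric()))
  }
  refine <- purrr::map(i, function(j) {
    y <- x[(j - 1):(j + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom >= 0) {
      return(c(time = t[j], amplitude = x[j]))
    }
    delta <- 0.5 * (y[1] - y[3]) / denom
    dtg <- t[j + 1] - t[j]
    c(time = t[j] + delta * dtg,
      amplitude = y[2] - 0.25 * (y[1] - y[3]) * delta)
  })
  m <- do.call(rbind, refine)
  tibble::tibble(time = m[, "time"], amplitude = m[, "amplitude"])
}

#' @export
#' @method print ews_recovery
print.ews_recovery <- function(x, ...) {
  cat(sprintf("<ews_recovery> lambda_hat = %.5g /y from %d peaks\n",
              x$lambda_hat, nrow(x$peaks)))
  invisible(x)
}

#' @rdname recovery_rate
#' @param x An `ews_recovery` object.
#' @param ... Unused.
#' @export
tidy.ews_recovery <- function(x, ...) {
  tibble::tibble(lambda_hat = x$lambda_hat, n_peaks = nrow(x$peaks))
}

#' Distance to the immunization threshold from fitted eigenvalue parts
#'
#' The complex modulus of the endemic eigenvalues satisfies
#' `|lambda|^2 = det(J) = mu (mu + gamma) (R0 (1 - nu) - 1)`, so a damping
#' rate and oscillation frequency estimated from data (e.g. by
#' [fit_damped_oscillation()]) invert to an estimate of the distance
#' `R0 (1 - nu) - 1` of the control parameter from its critical value.
#'
#' @param damping Estimated damping rate `|Re(lambda)|` (1/y).
#' @param frequency Estimated angular frequency `Im(lambda)` (1/y); must be
#'   positive (underdamped regime).
#' @param mu,gamma Death and recovery rates (1/y).
#' @return A one-row tibble with `distance` (the estimate of
#'   `R0 (1 - nu) - 1`) and `below_threshold` (`FALSE` when the estimate is
#'   not positive, flagging an at/over-threshold system).
#' @examples
#' distance_to_threshold(0.17, 2.2993, mu = 0.02, gamma = 365 / 22)
#' @export
distance_to_threshold <- function(damping, frequency, mu, gamma) {
  stopifnot(is.numeric(damping), is.numeric(frequency),
            mu > 0, gamma > 0)
  if (frequency <= 0) {
    stop("frequency must be positive (underdamped estimates required)",
         call. = FALSE)
  }
  est <- (damping^2 + frequency^2) / (mu * (mu + gamma))
  tibble::tibble(distance = est, below_threshold = est > 0)
}

# ---- shared helpers ----

detrend_values <- function(x, t, detrend) {
  if (detrend == "linear") {
    stats::lm.fit(cbind(1, t), x)$residuals
  } else {
    x - mean(x)
  }
}

check_series <- function(series) {
  stopifnot(
    "series must be a data frame with columns t, S, I" =
      is.data.frame(series) && all(c("t", "S", "I") %in% names(series))
  )
  if (nrow(series) == 0) stop("empty time series", call. = FALSE)
  if (any(diff(series$t) <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  invisible(series)
}

window_index <- function(t, window, stride, min_n = 10) {
  if (window > (max(t) - min(t))) {
    stop("window (", window, " y) is longer than the series", call. = FALSE)
  }
  centers <- seq(min(t) + window / 2, max(t) - window / 2, by = stride)
  out <- purrr::map(centers, function(ct) {
    idx <- which(t >= ct - window / 2 & t <= ct + window / 2)
    list(center = ct, idx = idx)
  })
  out <- purrr::keep(out, ~ length(.x$idx) >= min_n)
  if (length(out) == 0) {
    stop("no window contains at least ", min_n, " samples", call. = FALSE)
  }
  out
}
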