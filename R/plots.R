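#' Plot a simulated time series
#'
#' Susceptible and infected trajectories in stacked facets, with the uptake
#' schedule overlaid as a secondary track when it varies.
#'
#' @param object A `sir_timeseries` tibble.
#' @param vars Which state variables to show (default both).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sir_timeseries <- function(object, vars = c("S", "I"), ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "t", dplyr::all_of(vars)),
    -"t", names_to = "variable", values_to = "count"
  )
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$count)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = "count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ews_series <- function(object, ...) {
  value_cols <- intersect(
    c("var_S", "var_I", "gen_var", "acf_S", "acf_I"), names(object)
  )
  long <- tidyr::pivot_longer(
    dplyr::select(object, "window_center", dplyr::all_of(value_cols)),
    -"window_center", names_to = "indicator", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_center,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "window center (years)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Potential wells across vaccine uptakes
#'
#' The quadratic potential `V(z_I) = Delta z_I^2 / 2` of the linearized
#' infected deviation, one curve per uptake: wells get shallower as the
#' determinant shrinks toward the immunization threshold, the geometric
#' picture of critical slowing down.
#'
#' @param params A [sir_params()] tibble; `nu` is taken from `nus`.
#' @param nus Uptake values, one well per value.
#' @param prevalence_scale If `TRUE` (default), deviations are expressed in
#'   prevalence units by rescaling with `sqrt(b / mu)`.
#' @param z_range Range of deviations to plot (prevalence units when scaled).
#' @return A ggplot object.
#' @export
plot_potential <- function(params, nus = c(0.90, 0.92, 0.93, 0.9389),
                           prevalence_scale = TRUE, z_range = c(-2e-3, 2e-3)) {
  stopifnot(inherits(params, "sir_params"))
  scale <- if (prevalence_scale) sqrt(params$b / params$mu) else 1
  z <- seq(z_range[1], z_range[2], length.out = 201)
  curves <- purrr::map(nus, function(nu) {
    st <- stability(set_uptake(params, nu))
    tibble::tibble(nu = nu, z_I = z, V = potential(st$Delta, z, scale = scale))
  })
  d <- dplyr::bind_rows(curves)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_I, y = .data$V,
                                  colour = factor(.data$nu))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (prevalence_scale) "prevalence deviation" else
                    "deviation z_I",
                  y = "potential V", colour = "uptake") +
    ggplot2::theme_minimal()
}

#' Indicators across an uptake grid
#'
#' Variance of S and I, generalized variance and 95% ellipse area against
#' vaccine uptake, with the immunization threshold marked.
#'
#' @param scan Output of [variance_scan()].
#' @param nu_c Optional threshold uptake to mark with a dashed line.
#' @param log_scale Plot indicator values on a log axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_variance_scan <- function(scan, nu_c = NULL, log_scale = TRUE) {
  long <- tidyr::pivot_longer(
    dplyr::select(scan, "nu", "var_S", "var_I", "gen_var", "ellipse_area"),
    -"nu", names_to = "indicator", values_to = "value"
  )
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$nu, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "vaccine uptake", y = NULL) +
    ggplot2::theme_minimal()
  if (log_scale) g <- g + ggplot2::scale_y_log10()
  if (!is.null(nu_c)) {
    g <- g + ggplot2::geom_vline(xintercept = nu_c, linetype = "dashed",
                                 colour = "darkgreen")
  }
  g
}

#' 95% concentration ellipses across uptakes
#'
#' Draws the stationary-fluctuation concentration ellipse of `(S, I)`
#' deviations for each uptake; the region is largest near the immunization
#' threshold.
#'
#' @param params A [sir_params()] tibble; `nu` is taken from `nus`.
#' @param nus Uptake values.
#' @param level Coverage (default 0.95).
#' @return A ggplot object.
#' @export
plot_ellipses <- function(params, nus = c(0.5, 0.8, 0.9, 0.93), level = 0.95) {
  stopifnot(inherits(params, "sir_params"))
  theta <- seq(0, 2 * pi, length.out = 181)
  rings <- purrr::map(nus, function(nu) {
    p <- set_uptake(params, nu)
    eq <- default_equilibrium(p)
    J <- jacobian(p, eq$S, eq$I)
    Sigma <- stationary_covariance(J, diffusion_matrix(p, eq$S, eq$I))
    es <- eigen(Sigma, symmetric = TRUE)
    q <- sqrt(stats::qchisq(level, df = 2))
    pts <- es$vectors %*% rbind(q * sqrt(es$values[1]) * cos(theta),
                                q * sqrt(es$values[2]) * sin(theta))
    tibble::tibble(nu = nu, z_S = pts[1, ], z_I = pts[2, ])
  })
  d <- dplyr::bind_rows(rings)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_S, y = .data$z_I,
                                  colour = factor(.data$nu))) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "deviation of S", y = "deviation of I",
                  colour = "uptake") +
    ggplot2::theme_minimal()
}
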