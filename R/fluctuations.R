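#' Demographic-noise covariance (diffusion) matrix
#'
#' Covariance of the Gaussian white-noise forcing in the
#' diffusion approximation of the model, evaluated at a state `(S, I)`:
#' \deqn{B = \begin{pmatrix}
#'   \beta S I + \eta S + b(1-\nu) + \mu S & -(\beta S I + \eta S) \\
#'   -(\beta S I + \eta S) & \beta S I + \eta S + (\gamma + \mu) I
#' \end{pmatrix}}
#' Each entry is the per-year event-rate bookkeeping of demographic
#' stochasticity: diagonal entries sum the rates of all events that move the
#' variable, and the off-diagonal carries (with a minus sign) the infection
#' events that move both at once.
#'
#' @param params A [sir_params()] tibble.
#' @param S,I Nonnegative state (defaults: the default equilibrium).
#' @return A symmetric positive-semidefinite 2x2 matrix (individuals^2 / y).
#' @export
diffusion_matrix <- function(params, S = NULL, I = NULL) {
  stopifnot(inherits(params, "sir_params"))
  if (is.null(S) || is.null(I)) {
    eq <- default_equilibrium(params)
    S <- eq$S
    I <- eq$I
  }
  if (S < 0 || I < 0) stop("state (S, I) must be nonnegative", call. = FALSE)
  p <- params
  inf <- p$beta * S * I + p$eta * S
  matrix(
    c(inf + p$b * (1 - p$nu) + p$mu * S, -inf,
      -inf,                               inf + (p$gamma + p$mu) * I),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("S", "I"), c("S", "I"))
  )
}

#' Stationary covariance of the linear-noise fluctuations
#'
#' For fluctuations `dz = J z dt + dW` with noise covariance `B`, the
#' stationary distribution is bivariate normal with covariance `Sigma`
#' solving the continuous Lyapunov equation
#' `J Sigma + Sigma J^T + B = 0`.  For the symmetric 2x2 case this is a
#' 3-unknown linear system, solved exactly.
#'
#' @param J 2x2 Jacobian with all eigenvalues in the left half plane.
#' @param B 2x2 symmetric noise covariance.
#' @return The symmetric positive-definite 2x2 stationary covariance
#'   (individuals^2).
#' @export
stationary_covariance <- function(J, B) {
  stopifnot(is.matrix(J), all(dim(J) == c(2, 2)),
            is.matrix(B), all(dim(B) == c(2, 2)),
            isTRUE(all.equal(B[1, 2], B[2, 1])))
  ev <- eigen(J, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) {
    stop("J is not stable: no stationary distribution exists", call. = FALSE)
  }
  # unknowns (s11, s12, s22); rows: (1,1), (1,2), (2,2) of J Sigma + Sigma J^T
  A <- matrix(c(
    2 * J[1, 1], 2 * J[1, 2],           0,
    J[2, 1],     J[1, 1] + J[2, 2],     J[1, 2],
    0,           2 * J[2, 1],           2 * J[2, 2]
  ), nrow = 3, byrow = TRUE)
  s <- solve(A, -c(B[1, 1], B[1, 2], B[2, 2]))
  matrix(c(s[1], s[2], s[2], s[3]), 2, 2,
         dimnames = list(c("S", "I"), c("S", "I")))
}

#' Generalized variance
#'
#' Determinant of a variance-covariance matrix: a single multivariate spread
#' summary, proportional to the squared area of any fixed-coverage
#' concentration ellipse.
#'
#' @param Sigma A covariance matrix.
#' @return `det(Sigma)` (individuals^4 for an `(S, I)` covariance).
#' @export
generalized_variance <- function(Sigma) {
  stopifnot(is.matrix(Sigma), nrow(Sigma) == ncol(Sigma))
  det(Sigma)
}

#' 95% concentration ellipse of a bivariate normal
#'
#' Smallest region containing 95% of deviations under the stationary
#' bivariate normal: the ellipse `z^T Sigma^{-1} z <= q` with `q` the 0.95
#' quantile of the chi-square distribution with 2 degrees of freedom.  Its
#' area is `pi q sqrt(det Sigma)`, so area squared is proportional to the
#' generalized variance.
#'
#' @param Sigma Positive-definite 2x2 covariance matrix.
#' @param level Coverage probability (default 0.95).
#' @return A one-row tibble with `area`, semi-axes `a` >= `b` (individuals)
#'   and `angle` (radians, orientation of the major axis).
#' @export
ellipse_95 <- function(Sigma, level = 0.95) {
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == c(2, 2)))
  es <- eigen(Sigma, symmetric = TRUE)
  if (any(es$values <= 0)) {
    stop("Sigma must be positive definite", call. = FALSE)
  }
  q <- stats::qchisq(level, df = 2)
  axes <- sqrt(q * es$values)
  tibble::tibble(
    area = pi * q * sqrt(es$values[1] * es$values[2]),
    a = axes[1], b = axes[2],
    angle = atan2(es$vectors[2, 1], es$vectors[1, 1])
  )
}

#' Lagged autocovariance of stationary fluctuations
#'
#' The autocovariance of the stationary linear-noise process at nonnegative
#' lag is the matrix exponential of the Jacobian times the lag, applied to
#' the stationary covariance: `C(lag) = exp(J lag) Sigma`; negative lags
#' follow by transposition.
#'
#' @param J Stable 2x2 Jacobian.
#' @param Sigma Stationary covariance from [stationary_covariance()].
#' @param lag Lag in years.
#' @param normalize If `TRUE`, divide entry `(i, j)` by
#'   `sqrt(Sigma[i,i] Sigma[j,j])` so the diagonal holds per-variable
#'   autocorrelation functions.
#' @return A 2x2 matrix.
#' @export
autocovariance <- function(J, Sigma, lag, normalize = FALSE) {
  stopifnot(is.matrix(J), all(dim(J) == c(2, 2)),
            is.matrix(Sigma), all(dim(Sigma) == c(2, 2)),
            is.numeric(lag), length(lag) == 1)
  C <- if (lag >= 0) {
    as.matrix(Matrix::expm(J * lag)) %*% Sigma
  } else {
    t(as.matrix(Matrix::expm(-J * lag)) %*% Sigma)
  }
  dimnames(C) <- dimnames(Sigma)
  if (normalize) {
    d <- sqrt(diag(Sigma))
    C <- C / outer(d, d)
  }
  C
}

#' Theoretical autocorrelation curves of S and I
#'
#' Per-variable autocorrelation functions of the stationary fluctuations at a
#' set of lags, from [autocovariance()].
#'
#' @param params A [sir_params()] tibble (analysed at its default
#'   equilibrium), or `NULL` to supply `J` and `Sigma` directly.
#' @param lags Numeric vector of nonnegative lags (years).
#' @param J,Sigma Optional explicit Jacobian and stationary covariance.
#' @return A tibble with columns `lag`, `acf_S`, `acf_I`.
#' @export
acf_theoretical <- function(params = NULL, lags = seq(0, 10, by = 0.1),
                            J = NULL, Sigma = NULL) {
  if (is.null(J) || is.null(Sigma)) {
    stopifnot(inherits(params, "sir_params"))
    eq <- default_equilibrium(params)
    J <- jacobian(params, eq$S, eq$I)
    Sigma <- stationary_covariance(J, diffusion_matrix(params, eq$S, eq$I))
  }
  rows <- purrr::map(lags, function(l) {
    C <- autocovariance(J, Sigma, l, normalize = TRUE)
    tibble::tibble(lag = l, acf_S = C[1, 1], acf_I = C[2, 2])
  })
  dplyr::bind_rows(rows)
}

#' Fluctuation summary across a grid of vaccine uptakes
#'
#' For each uptake on the grid, computes the equilibrium (the sparked branch
#' when `eta > 0`, else endemic below threshold / disease-free above), the
#' linear-noise stationary covariance, the generalized variance, the 95%
#' ellipse area and the dominant eigenvalue.  Grid points whose equilibrium
#' is not stable (so no stationary distribution exists) are flagged with
#' `stable = FALSE` and `NA` moments.
#'
#' @param params A [sir_params()] tibble; its `nu` entry is ignored.
#' @param nu_grid Vector of uptakes in `[0, 1)`.
#' @return A tibble with columns `nu`, `S_star`, `I_star`, `var_S`, `var_I`,
#'   `cov_SI`, `gen_var`, `ellipse_area`, `re_lambda`, `im_lambda`, `stable`.
#' @examples
#' variance_scan(sir_params(), nu_grid = seq(0.85, 0.94, by = 0.01))
#' @export
variance_scan <- function(params, nu_grid) {
  stopifnot(inherits(params, "sir_params"),
            is.numeric(nu_grid), all(nu_grid >= 0), all(nu_grid < 1))
  rows <- purrr::map(nu_grid, function(nu) {
    p <- set_uptake(params, nu)
    eq <- default_equilibrium(p)
    st <- stability(p)
    lam <- st$eigenvalues[1]
    base <- tibble::tibble(
      nu = nu, S_star = eq$S, I_star = eq$I,
      re_lambda = Re(lam), im_lambda = Im(lam)
    )
    if (!all(Re(st$eigenvalues) < 0)) {
      return(dplyr::mutate(base,
        var_S = NA_real_, var_I = NA_real_, cov_SI = NA_real_,
        gen_var = NA_real_, ellipse_area = NA_real_, stable = FALSE
      ))
    }
    B <- diffusion_matrix(p, eq$S, eq$I)
    Sigma <- stationary_covariance(st$J, B)
    dplyr::mutate(base,
      var_S = Sigma[1, 1], var_I = Sigma[2, 2], cov_SI = Sigma[1, 2],
      gen_var = generalized_variance(Sigma),
      ellipse_area = ellipse_95(Sigma)$area,
      stable = TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "nu", "S_star", "I_star", "var_S", "var_I", "cov_SI",
                "gen_var", "ellipse_area", "re_lambda", "im_lambda", "stable")
}
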