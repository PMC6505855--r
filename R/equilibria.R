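#' Equilibria of the SIR model with vaccination
#'
#' Fixed points of the deterministic drift.  Without sparking (`eta = 0`) the
#' model has a disease-free equilibrium `(N(1 - nu), 0)` for every uptake, and
#' an endemic equilibrium `(N / R0, (mu / beta) [R0 (1 - nu) - 1])` whenever
#' `R0 (1 - nu) > 1`; the two exchange stability at the immunization threshold
#' (a transcritical bifurcation).  With sparking (`eta > 0`) case importation
#' keeps prevalence positive at every uptake and the model has a single
#' admissible equilibrium, found by eliminating `S` from the steady-state
#' conditions and solving the resulting quadratic in `I`.
#'
#' @param params A [sir_params()] tibble.
#' @return A tibble with one row per equilibrium and columns `branch`
#'   (`"disease_free"`, `"endemic"` or `"sparked"`), `S`, `I`, and `stable`
#'   (local asymptotic stability from the Jacobian eigenvalues).
#'
#' @examples
#' equilibria(sir_params(nu = 0.9, eta = 0))
#' equilibria(sir_params(nu = 0.95)) # above threshold, sparking keeps I > 0
#' @export
equilibria <- function(params) {
  stopifnot(inherits(params, "sir_params"))
  p <- params
  if (p$eta == 0) {
    out <- tibble::tibble(
      branch = "disease_free", S = p$N * (1 - p$nu), I = 0
    )
    x <- p$R0 * (1 - p$nu)
    if (x > 1) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        branch = "endemic",
        S = p$N / p$R0,
        I = (p$mu / p$beta) * (x - 1)
      ))
    }
  } else {
    eq <- sparked_equilibrium(p)
    out <- tibble::tibble(branch = "sparked", S = eq[["S"]], I = eq[["I"]])
  }
  out$stable <- vapply(seq_len(nrow(out)), function(i) {
    ev <- eigen(jacobian(p, S = out$S[i], I = out$I[i]),
                only.values = TRUE)$values
    all(Re(ev) < 1e-12)
  }, logical(1))
  out
}

# Steady state of the drift when eta > 0: eliminating S gives
#   (gamma+mu) beta I^2 - [b(1-nu) beta - (gamma+mu)(eta+mu)] I - b(1-nu) eta = 0
# whose product of roots is <= 0, so exactly one root is nonnegative.
sparked_equilibrium <- function(p) {
  a <- (p$gamma + p$mu) * p$beta
  bq <- -(p$b * (1 - p$nu) * p$beta - (p$gamma + p$mu) * (p$eta + p$mu))
  cq <- -p$b * (1 - p$nu) * p$eta
  disc <- bq^2 - 4 * a * cq
  stopifnot("no real equilibrium root (cannot occur for valid params)" =
              disc >= 0)
  I <- (-bq + sqrt(disc)) / (2 * a)
  S <- (p$b * (1 - p$nu) - (p$gamma + p$mu) * I) / p$mu
  stopifnot("negative equilibrium (cannot occur for valid params)" =
              I >= 0 && S >= 0)
  c(S = S, I = I)
}

# Pick the default equilibrium for analysis: the sparked one when eta > 0,
# else endemic below threshold, else disease-free.
default_equilibrium <- function(params, branch = c("auto", "endemic",
                                                   "disease_free", "sparked")) {
  branch <- match.arg(branch)
  eqs <- equilibria(params)
  if (branch == "auto") {
    i <- if ("sparked" %in% eqs$branch) {
      which(eqs$branch == "sparked")
    } else if ("endemic" %in% eqs$branch) {
      which(eqs$branch == "endemic")
    } else {
      which(eqs$branch == "disease_free")
    }
  } else {
    i <- which(eqs$branch == branch)
    if (length(i) == 0) {
      stop("no '", branch, "' equilibrium for these parameters", call. = FALSE)
    }
  }
  eqs[i, ]
}
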