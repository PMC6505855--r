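test_that("threshold uptake follows 1 - 1/R0", {
  expect_equal(threshold_uptake(sir_params(R0 = 17)), 1 - 1 / 17)
  expect_equal(round(threshold_uptake(sir_params(R0 = 17)), 3), 0.941)
  expect_equal(threshold_uptake(sir_params(R0 = 1)), 0)
  expect_equal(threshold_uptake(sir_params(R0 = 2)), 0.5)
  expect_message(
    expect_lt(threshold_uptake(sir_params(R0 = 0.8)), 0),
    "not sustained"
  )
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(sir_params(nu = 1.2), "nu")
  expect_error(sir_params(mu = -0.1), "mu")
  expect_error(sir_params(R0 = 0), "R0")
  p <- sir_params()
  expect_gt(p$N, 0)
  expect_gt(p$beta, 0)
  expect_equal(p$R0, p$N * p$beta / (p$gamma + p$mu))
})

test_that("sparking-free equilibria match the closed forms", {
  p <- fig_params(nu = 0.9, eta = 0)
  eq <- equilibria(p)
  expect_setequal(eq$branch, c("disease_free", "endemic"))
  en <- eq[eq$branch == "endemic", ]
  expect_equal(en$S, p$N / p$R0)
  expect_equal(en$S, 588235.29, tolerance = 1e-6)
  expect_equal(en$I, (p$mu / p$beta) * (p$R0 * (1 - p$nu) - 1))
  expect_equal(en$I, 495.78, tolerance = 1e-4)
  expect_true(en$stable)
  expect_false(eq$stable[eq$branch == "disease_free"])

  # above threshold only the (stable) disease-free state remains
  eq_hi <- equilibria(fig_params(nu = 0.96, eta = 0))
  expect_equal(eq_hi$branch, "disease_free")
  expect_true(eq_hi$stable)
})

test_that("endemic branch meets the disease-free branch at the threshold", {
  p <- fig_params(eta = 0)
  nu_c <- threshold_uptake(p)
  # endemic I* shrinks continuously to zero as nu -> nu_c from below
  nus <- nu_c - c(1e-2, 1e-3, 1e-4, 1e-6)
  Is <- vapply(nus, function(nu) {
    endemic_eq(set_uptake(p, nu))$I
  }, numeric(1))
  expect_true(all(diff(Is) < 0))
  expect_lt(Is[4], 1e-2 * Is[1])
  expect_equal(Is / ((p$mu / p$beta) * p$R0 * (nu_c - nus)), rep(1, 4))
})

test_that("sparked equilibrium agrees with relaxing the noise-free dynamics", {
  p <- fig_params(nu = 0.95) # above threshold: sparking keeps I* > 0
  eq <- equilibria(p)
  expect_equal(eq$branch, "sparked")
  expect_gt(eq$I, 0)
  # oracle: integrate the deterministic drift to steady state
  ts <- ode_trajectory(p, T = 2000, init = c(S = p$N * 0.04, I = 10),
                       sample_dt = 10)
  expect_equal(tail(ts$S, 1), eq$S, tolerance = 1e-6)
  expect_equal(tail(ts$I, 1), eq$I, tolerance = 1e-6)
  # sparked prevalence is positive at every uptake, including nu = 1
  for (nu in c(0, 0.5, 0.941, 0.99)) {
    expect_gt(equilibria(set_uptake(p, nu))$I, 0)
  }
})

test_that("Jacobian matches its closed-form eigenstructure", {
  # disease-free: eigenvalues -mu and (gamma+mu)[R0(1-nu)-1]
  p <- fig_params(nu = 0.5, eta = 0)
  eq <- equilibria(p)
  df <- eq[eq$branch == "disease_free", ]
  ev <- sort(Re(eigen(jacobian(p, df$S, df$I))$values))
  expected <- sort(c(-p$mu, (p$gamma + p$mu) * (p$R0 * (1 - p$nu) - 1)))
  expect_equal(ev, expected)

  # beta = 0 decouples the system: J diagonal with -mu and -(gamma+mu)
  p0 <- sir_params(R0 = 1e-12, eta = 0, nu = 0.3)
  J0 <- jacobian(p0, S = 1000, I = 10)
  expect_equal(J0[1, 2], 0, tolerance = 1e-6)
  expect_equal(J0[2, 1], 0, tolerance = 1e-12)
  expect_equal(diag(J0), c(S = -p0$mu, I = -(p0$gamma + p0$mu)),
               tolerance = 1e-9)

  # endemic trace and determinant at nu = 0
  st <- stability(fig_params(nu = 0, eta = 0), branch = "endemic")
  expect_equal(st$tau, -0.34)
  expect_equal(st$Delta, 5.3155, tolerance = 1e-4)
})

test_that("endemic spectrum matches the damped-oscillator summary", {
  st <- stability(fig_params(nu = 0, eta = 0), branch = "endemic")
  expect_equal(st$eigenvalues[1], complex(real = -0.17, imaginary = 2.2993),
               tolerance = 1e-4)
  expect_equal(st$period, 2.733, tolerance = 1e-3)
  expect_equal(st$zeta, 0.0737, tolerance = 1e-3)
  expect_equal(st$modulus, sqrt(st$Delta))
  expect_match(st$regime, "stable underdamped")
  g <- glance(st)
  expect_equal(g$zeta, st$zeta)
  expect_equal(nrow(tidy(st)), 2)
})

test_that("trace/determinant identities hold and the threshold eigenvalue is zero", {
  p <- fig_params(nu = 1 - 1 / 17, eta = 0) # exactly at threshold
  st <- stability(p, branch = "disease_free")
  expect_lt(abs(Re(st$eigenvalues[1])), 1e-10)
  # tau = sum of eigenvalues, Delta = product, modulus^2 = Delta when complex
  st2 <- stability(fig_params(nu = 0.5, eta = 0), branch = "endemic")
  expect_equal(st2$tau, sum(Re(st2$eigenvalues)))
  expect_equal(st2$Delta, Re(prod(st2$eigenvalues)))
  expect_equal(st2$modulus^2, st2$Delta)
  expect_true((st2$zeta < 1) == any(Im(st2$eigenvalues) != 0))
})

test_that("numerical eigenvalues match the endemic closed form across random draws", {
  set.seed(41)
  for (i in 1:20) {
    p <- random_endemic_params()
    st <- stability(p, branch = "endemic")
    x <- p$R0 * (1 - p$nu)
    re <- -p$mu * x / 2
    disc <- (p$mu * x)^2 / 4 - p$mu * (x - 1) * (p$mu + p$gamma)
    expected <- if (disc >= 0) {
      sort(c(re + sqrt(disc), re - sqrt(disc)))
    } else {
      sort(c(re, re)) # real parts; imaginary checked separately
    }
    if (disc < 0) {
      expect_equal(Re(st$eigenvalues), c(re, re), tolerance = 1e-10)
      expect_equal(sort(Im(st$eigenvalues)),
                   c(-sqrt(-disc), sqrt(-disc)), tolerance = 1e-10)
    } else {
      expect_equal(sort(Re(st$eigenvalues)), expected, tolerance = 1e-10)
      expect_equal(Im(st$eigenvalues), c(0, 0))
    }
  }
})

test_that("return rate grows with distance from the threshold on both sides", {
  p <- fig_params(eta = 0)
  nu_c <- threshold_uptake(p)
  # below: dominant eigenvalue real part of the endemic equilibrium
  below <- vapply(nu_c - c(0.002, 0.01, 0.05, 0.2, 0.5), function(nu) {
    Re(stability(set_uptake(p, nu), branch = "endemic")$eigenvalues[1])
  }, numeric(1))
  expect_true(all(diff(abs(below)) > 0))
  # above: the dominant disease-free eigenvalue (gamma+mu)[R0(1-nu)-1] until
  # it crosses -mu, after which -mu takes over; stay inside that window
  above <- vapply(nu_c + c(1e-5, 2e-5, 4e-5, 6e-5), function(nu) {
    Re(stability(set_uptake(p, nu), branch = "disease_free")$eigenvalues[1])
  }, numeric(1))
  expect_true(all(above < 0))
  expect_true(all(diff(abs(above)) > 0))
  # and the epidemic-direction eigenvalue keeps steepening farther out
  steep <- vapply(nu_c + c(0.002, 0.01, 0.03), function(nu) {
    min(Re(stability(set_uptake(p, nu), branch = "disease_free")$eigenvalues))
  }, numeric(1))
  expect_true(all(diff(abs(steep)) > 0))
})

test_that("closed-form eigenvalue approximations evaluate correctly", {
  p <- fig_params(nu = 0, eta = 0)
  ap <- eigenvalue_approximations(p)
  expect_equal(ap$im_approx, sqrt(0.02 * 16 * 365 / 22), tolerance = 1e-12)
  expect_equal(ap$re_approx, -0.17)
  # approximation error below 1% for mu << gamma, R0(1-nu) >> 1
  st <- stability(p, branch = "endemic")
  expect_lt(abs(ap$im_approx - Im(st$eigenvalues[1])) / Im(st$eigenvalues[1]),
            0.01)
  expect_error(eigenvalue_approximations(fig_params(nu = 0.95)), "exceed 1")
})

test_that("the inter-epidemic period formula recovers the eigenvalue period", {
  p <- fig_params(nu = 0, eta = 0)
  pp <- period_prediction(p)
  expect_equal(pp$A, 3.125)
  expect_equal(pp$D, 22 / 365)
  expect_equal(pp$period_approx, 2 * pi * sqrt(pp$A * pp$D))
  expect_equal(pp$period_approx, 2.727, tolerance = 1e-3)
  expect_equal(pp$period_exact, 2.733, tolerance = 1e-3)
  expect_lt(abs(pp$period_approx - pp$period_exact) / pp$period_exact, 0.003)
  # period lengthens monotonically on the way to the threshold
  periods <- vapply(c(0, 0.5, 0.9, 0.93), function(nu) {
    period_prediction(set_uptake(p, nu))$period_approx
  }, numeric(1))
  expect_true(all(diff(periods) > 0))
  expect_error(period_prediction(set_uptake(p, 0.95)), "threshold")
})

test_that("potential wells are quadratic and shallow near the threshold", {
  expect_equal(potential(2, 0), 0)
  expect_equal(potential(2, 1), 1)
  expect_equal(potential(3, c(-2, 2)), c(6, 6))
  # fixed deviation: wells get shallower as uptake rises toward nu_c
  p <- fig_params(eta = 0)
  V <- vapply(c(0.85, 0.9, 0.93), function(nu) {
    potential(stability(set_uptake(p, nu), branch = "endemic")$Delta, 100)
  }, numeric(1))
  expect_true(all(diff(V) < 0))
  # prevalence rescaling enters as a squared factor
  expect_equal(potential(2, 1, scale = 3), 9 * potential(2, 1))
})

test_that("underdamped boundary matches the damping quadratic and moves with gamma", {
  p <- fig_params()
  nu_star <- underdamped_boundary(p)
  expect_equal(round(nu_star, 3), 0.939)
  # eta = 0 limit: zeta = 1 means mu x^2 = 4 (mu + gamma)(x - 1), x = R0(1 - nu)
  p0 <- fig_params(eta = 0)
  nu0 <- underdamped_boundary(p0, tol = 1e-12)
  x <- p0$R0 * (1 - nu0)
  expect_equal(p0$mu * x^2, 4 * (p0$mu + p0$gamma) * (x - 1),
               tolerance = 1e-7)
  # direct quadratic solution as an independent oracle
  roots <- sort(Re(polyroot(c(4 * (p0$mu + p0$gamma),
                              -4 * (p0$mu + p0$gamma), p0$mu))))
  expect_equal(x, roots[1], tolerance = 1e-8)
  # as gamma grows the boundary approaches the threshold from below
  nu_c <- threshold_uptake(p)
  bnds <- vapply(c(1, 2, 4), function(f) {
    pf <- sir_params(R0 = 17, b = 2e5, mu = 0.02, gamma = f * 365 / 22,
                     eta = 0, nu = 0)
    underdamped_boundary(pf)
  }, numeric(1))
  expect_true(all(diff(bnds) > 0))
  expect_true(all(bnds < nu_c))
  expect_error(underdamped_boundary(p, interval = c(0.1, 0.2)), "sign")
})

test_that("linearized deviations propagate by the matrix exponential", {
  J <- diag(c(-1, -2))
  expect_equal(
    as.numeric(linear_solution(J, c(1, 1), 0)[, c("z_S", "z_I")]),
    c(1, 1)
  )
  sol <- linear_solution(J, c(1, 1), log(2))
  expect_equal(c(sol$z_S, sol$z_I), c(0.5, 0.25))
  # envelope of the endemic spiral decays at |Re(lambda)| = 0.017 /y
  p <- fig_params(nu = 0.9, eta = 0)
  st <- stability(p, branch = "endemic")
  tt <- seq(0, 400, by = 0.05)
  traj <- linear_solution(st$J, c(0, st$I * 0.5), tt)
  pk <- sirews:::find_peaks(traj$t, abs(traj$z_I))
  rate <- -stats::coef(stats::lm(log(amplitude) ~ time, data = pk))[[2]]
  expect_equal(rate, abs(Re(st$eigenvalues[1])), tolerance = 0.02)
})
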