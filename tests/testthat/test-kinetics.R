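test_that("pc_count follows the exponential decay solution", {
  expect_equal(pc_count(10, kinetic_params(n0 = 100, beta = 0)), 100)
  expect_equal(pc_count(1, kinetic_params(n0 = 1, beta = 1)), 0.367879,
               tolerance = 1e-5)
  # at one half-life exactly half the initial population remains
  p <- kinetic_params(n0 = 5e5, beta = 0.005)
  expect_equal(pc_count(half_life(0.005), p), 2.5e5, tolerance = 1e-10)
  expect_equal(pc_count(0, p), p$n0)
  # nonincreasing in t
  tt <- seq(0, 400, by = 5)
  expect_true(all(diff(pc_count(tt, p)) <= 0))
  expect_error(pc_count(-1, p), "nonnegative")
})

test_that("antibody_amount matches the closed form and its lam = beta limit", {
  p <- kinetic_params(n0 = 1, beta = 0.005, gamma = 1, lam = 0.1)
  expect_equal(antibody_amount(0, p), 0)
  expect_equal(antibody_amount(14, p), 7.2189, tolerance = 1e-4)
  # removable singularity: limit form gamma*n0*t*exp(-beta*t)
  peq <- kinetic_params(n0 = 1, beta = 0.1, gamma = 1, lam = 0.1)
  expect_equal(antibody_amount(10, peq), 10 * exp(-1), tolerance = 1e-12)
  # nonnegative for all t
  expect_true(all(antibody_amount(seq(0, 365, by = 1), p) >= 0))
})

test_that("closed form is continuous across the lam -> beta singularity", {
  for (beta in c(0.005, 0.05, 0.5)) {
    p_lim <- kinetic_params(n0 = 1e5, beta = beta, gamma = 20, lam = beta)
    p_eps <- kinetic_params(n0 = 1e5, beta = beta, gamma = 20,
                            lam = beta * (1 + 1e-6))
    for (t in c(1, 10, 100)) {
      lim <- 20 * 1e5 * t * exp(-beta * t)
      expect_equal(antibody_amount(t, p_lim), lim, tolerance = 1e-12)
      expect_equal(antibody_amount(t, p_eps), lim, tolerance = 1e-5)
    }
  }
})

test_that("igg_concentration bridges amount to serum concentration", {
  # 1.5e6 pg in 1.5 mL is 1e6 pg/mL = 1000 ng/mL
  p <- kinetic_params(n0 = 1, beta = 0, gamma = 1, lam = 1, plasma_volume = 1.5)
  t_for_amount <- 14
  amt <- antibody_amount(t_for_amount, p)
  expect_equal(igg_concentration(t_for_amount, p), amt / 1.5 / 1000)
  p1 <- kinetic_params(n0 = 1, beta = 0.005, gamma = 1, lam = 0.1,
                       plasma_volume = 1)
  expect_equal(igg_concentration(14, p1), 7.2189e-3, tolerance = 1e-4)
  expect_equal(igg_concentration(0, p1), 0)
})

test_that("ode_rhs returns the coupled derivatives", {
  p <- kinetic_params(n0 = 100, beta = 0.005, gamma = 50, lam = 0.1)
  expect_equal(ode_rhs(c(0, 0), p), c(0, 0))
  expect_equal(ode_rhs(c(100, 0), p), c(-0.5, 5000))
  # steady-state balance gamma*N = lam*G gives dG/dt = 0
  expect_equal(ode_rhs(c(100, 50000), p)[2], 0)
  expect_error(ode_rhs(c(-1, 0), p), "nonnegative")
})

test_that("peak_time is the symmetric analytic maximiser of the curve", {
  expect_equal(peak_time(0.1, 0.1), 10)
  expect_equal(peak_time(0.005, 0.1), log(20) / 0.095, tolerance = 1e-12)
  expect_equal(peak_time(0.005, 0.1), 31.53, tolerance = 1e-3)
  expect_equal(peak_time(0.005, 0.1), peak_time(0.1, 0.005))
  # evaluating neighbours confirms the maximum
  p <- kinetic_params(n0 = 1e5, beta = 0.005, gamma = 50, lam = 0.1)
  tp <- peak_time(p$beta, p$lam)
  g <- antibody_amount(c(tp - 0.5, tp, tp + 0.5), p)
  expect_true(g[2] > g[1] && g[2] > g[3])
  # increasing before the peak, decreasing after
  tt <- seq(0, 365, by = 0.5)
  gg <- antibody_amount(tt, p)
  expect_true(all(diff(gg[tt < tp - 0.5]) > 0))
  expect_true(all(diff(gg[tt > tp + 0.5]) < 0))
  expect_error(peak_time(0, 0.1), "positive")
})

test_that("half_life inverts the decay rate", {
  expect_equal(half_life(0.005), 138.6, tolerance = 1e-3)
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.01), 69.31, tolerance = 1e-3)
  expect_error(half_life(0), "positive")
})

test_that("cumulative secretion rate equals gamma * N(t)", {
  # d/dt integral of gamma*N equals gamma*N: check the quadrature of
  # gamma*N against the G-production implied by the ODE over [0, T]
  p <- kinetic_params(n0 = 1e5, beta = 0.02, gamma = 10, lam = 0.3)
  cum_secreted <- function(T) {
    stats::integrate(function(u) p$gamma * pc_count(u, p), 0, T,
                     rel.tol = 1e-10)$value
  }
  # analytic: gamma*n0*(1 - e^{-beta T})/beta
  for (T in c(5, 50, 200)) {
    expect_equal(cum_secreted(T), p$gamma * p$n0 * (1 - exp(-p$beta * T)) / p$beta,
                 tolerance = 1e-8)
  }
})

test_that("biphasic survival generalises the single exponential", {
  bp0 <- biphasic_params(beta0 = 0.1, beta1 = 0)
  expect_equal(biphasic_survival(0, bp0), 1)
  expect_equal(biphasic_survival(10, bp0), exp(-1), tolerance = 1e-12)
  # beta1 = 0 equals pc_count/n0 exactly on a grid
  p <- kinetic_params(n0 = 1e4, beta = 0.1)
  tt <- seq(0, 21, by = 0.5)
  expect_equal(biphasic_survival(tt, bp0), pc_count(tt, p) / p$n0,
               tolerance = 1e-15)
  # decelerating decay example
  bp <- suppressWarnings(biphasic_params(beta0 = 0.2, beta1 = -0.005))
  expect_equal(biphasic_survival(10, bp), exp(-1.5), tolerance = 1e-12)
  expect_equal(biphasic_survival(10, bp), 0.22313, tolerance = 1e-4)
})

test_that("biphasic validity window is enforced by reporting", {
  # rate 0.3 - 0.02 t goes negative at t = 15 < 21: flagged, not refused
  expect_warning(bp <- biphasic_params(0.3, -0.01, window_end = 21),
                 "negative")
  expect_false(bp$rate_nonneg)
  expect_equal(suppressWarnings(biphasic_survival(21, bp)),
               exp(-1.89), tolerance = 1e-6)
  # extrapolation beyond the window warns but computes
  bp_ok <- biphasic_params(0.25, -0.0058, window_end = 21)
  expect_true(bp_ok$rate_nonneg)
  expect_warning(v <- biphasic_survival(30, bp_ok), "window")
  expect_equal(v, exp(-(0.25 * 30 - 0.0058 * 900)), tolerance = 1e-12)
})

test_that("instantaneous decay rate is the derivative of the exponent", {
  bp <- suppressWarnings(biphasic_params(0.2, -0.005))
  expect_equal(instantaneous_decay_rate(0, bp), 0.2)
  expect_equal(instantaneous_decay_rate(10, bp), 0.1)
  bp0 <- biphasic_params(0.07, 0)
  expect_equal(instantaneous_decay_rate(c(0, 5, 21), bp0), rep(0.07, 3))
  # numerical derivative of -log survival agrees
  h <- 1e-6
  t0 <- 4
  num <- (log(suppressWarnings(biphasic_survival(t0 - h, bp))) -
            log(suppressWarnings(biphasic_survival(t0 + h, bp)))) / (2 * h)
  expect_equal(instantaneous_decay_rate(t0, bp), num, tolerance = 1e-6)
})

test_that("parameter constructors validate their domains", {
  expect_error(kinetic_params(n0 = -1, beta = 0.005), "n0")
  expect_error(kinetic_params(n0 = 1, beta = -0.1), "beta")
  expect_error(kinetic_params(lam = 0), "lam")
  expect_error(kinetic_params(plasma_volume = 0), "plasma_volume")
  expect_error(kinetic_params(gamma = -5), "gamma")
  # beta and lam may be equal without error
  expect_silent(kinetic_params(n0 = 1, beta = 0.1, lam = 0.1))
})
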