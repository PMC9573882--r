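test_that("long-term fit recovers exact parameters from noiseless data", {
  p <- kinetic_params(n0 = 5e5, beta = 0.005)
  s <- make_igg_series(p, c(21, 30, 60, 90, 180, 365))
  f <- fit_longterm(s)
  expect_true(f$converged)
  expect_equal(f$estimate$n0, 5e5, tolerance = 1e-4)
  expect_equal(f$estimate$beta, 0.005, tolerance = 1e-4)
  expect_lt(f$rss, 1e-12)
  expect_equal(f$n_obs, 6)
  expect_equal(f$fit_window, c(21, 365))
  # log-loss route agrees on noiseless data
  f_log <- fit_longterm(s, loss = "log")
  expect_equal(f_log$estimate$beta, 0.005, tolerance = 1e-4)
})

test_that("a flat plateau yields a near-zero decay rate", {
  p <- kinetic_params(n0 = 2e5, beta = 0)
  s <- make_igg_series(p, c(30, 60, 120, 240, 365))
  f <- fit_longterm(s)
  expect_lt(f$estimate$beta, 1e-6)
  expect_equal(f$estimate$n0, 2e5, tolerance = 1e-3)
})

test_that("fit window and data preconditions are enforced", {
  p <- kinetic_params(n0 = 5e5, beta = 0.005)
  # points before t_min are excluded, leaving too few
  s <- make_igg_series(p, c(3, 7, 14, 30, 60))
  expect_error(fit_longterm(s), "insufficient data")
  expect_silent(f <- fit_longterm(s, t_min = 7))
  expect_equal(f$n_obs, 4)
  expect_error(fit_longterm(s, constants = kinetic_params(gamma = 0)),
               "gamma")
})

test_that("decay rate is recovered within 15% median error under ELISA noise", {
  set.seed(482911)
  truth <- kinetic_params(n0 = 5e5, beta = 0.005)
  days <- c(21, 30, 60, 90, 180, 365)
  clean <- igg_concentration(days, truth)
  rel_err <- replicate(200, {
    y <- clean * exp(rnorm(length(days), 0, 0.2))
    s <- time_series("m", "control", days, y)
    # log-scale loss matches the multiplicative ELISA noise
    f <- fit_longterm(s, loss = "log")
    abs(f$estimate$beta - 0.005) / 0.005
  })
  expect_lt(median(rel_err), 0.15)
})

test_that("constant-decay fit is exact on pure exponential counts", {
  days <- c(0, 3, 7, 14, 21)
  s <- time_series("r1", "vehicle", days, 1e4 * exp(-0.1 * days),
                   value_kind = "cell_count")
  f <- fit_constant_decay(s)
  expect_equal(f$estimate$beta0, 0.1, tolerance = 1e-4)
  expect_lt(f$rss, 1e-10)
  # three exact points saturate the single-parameter fit
  s3 <- time_series("r2", "vehicle", c(0, 5, 10), 100 * exp(-0.2 * c(0, 5, 10)),
                    value_kind = "cell_count")
  expect_lt(fit_constant_decay(s3)$rss, 1e-12)
})

test_that("biphasic fit is exact on noiseless biphasic data", {
  days <- c(0, 2, 4, 6, 10, 14, 21)
  surv <- exp(-(0.3 * days - 0.01 * days^2))
  s <- time_series("r1", "vehicle", days, 1e6 * surv,
                   value_kind = "cell_count")
  f <- suppressWarnings(fit_biphasic_decay(s))
  expect_equal(f$estimate$beta0, 0.3, tolerance = 1e-6)
  expect_equal(f$estimate$beta1, -0.01, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("biphasic fit nests the constant-decay fit", {
  # on biphasic-truth data the constant model must fit strictly worse
  s <- suppressWarnings(
    simulate_decay_counts(beta0 = 0.3, beta1 = -0.01, n0_cells = 1e5,
                          noise_sigma_log = 0, seed = 1))
  fc <- fit_constant_decay(s)
  fb <- suppressWarnings(fit_biphasic_decay(s))
  expect_gt(fc$rss, fb$rss)
  # and on any data, noisy or not, rss(biphasic) <= rss(constant)
  for (seed in 1:10) {
    sn <- suppressWarnings(
      simulate_decay_counts(beta0 = 0.25, beta1 = -0.0058,
                            noise_sigma_log = 0.15, seed = seed))
    expect_lte(suppressWarnings(fit_biphasic_decay(sn))$rss,
               fit_constant_decay(sn)$rss)
  }
})

test_that("beta1 = 0 truth collapses the biphasic fit to the constant fit", {
  days <- c(0, 2, 4, 6, 10, 14, 21)
  s <- time_series("r1", "vehicle", days, 5e4 * exp(-0.08 * days),
                   value_kind = "cell_count")
  fb <- fit_biphasic_decay(s)
  fc <- fit_constant_decay(s)
  expect_equal(fb$estimate$beta1, 0, tolerance = 1e-6)
  expect_equal(fb$estimate$beta0, fc$estimate$beta0, tolerance = 1e-5)
})

test_that("regression and iterative biphasic routes agree on positive counts", {
  for (seed in 1:20) {
    s <- suppressWarnings(
      simulate_decay_counts(beta0 = 0.25, beta1 = -0.0058, n0_cells = 1e6,
                            noise_sigma_log = 0.05, seed = 1000 + seed))
    f_nls <- suppressWarnings(fit_biphasic_decay(s, route = "nls"))
    f_log <- suppressWarnings(fit_biphasic_decay(s, route = "loglinear"))
    expect_equal(f_nls$estimate$beta0, f_log$estimate$beta0, tolerance = 1e-3)
    expect_equal(f_nls$estimate$beta1, f_log$estimate$beta1, tolerance = 1e-3)
    expect_equal(f_nls$rss, f_log$rss, tolerance = 1e-6)
  }
})

test_that("zero counts force the nonlinear route and are reported", {
  days <- c(0, 2, 4, 6, 10, 14, 21)
  counts <- c(1000, 500, 260, 150, 60, 20, 0)
  s <- time_series("r1", "vehicle", days, counts, value_kind = "cell_count")
  expect_error(fit_biphasic_decay(s, route = "loglinear"), "positive")
  f <- suppressWarnings(fit_biphasic_decay(s))
  expect_equal(f$route, "nls")
  expect_true(f$converged)
})

test_that("gamma and n0 are identified only through their product", {
  set.seed(3317)
  days <- c(21, 30, 60, 90, 180, 365)
  truth <- kinetic_params(n0 = 3e5, beta = 0.006)
  y <- igg_concentration(days, truth) * exp(rnorm(length(days), 0, 0.1))
  s <- time_series("m", "hIL6", days, y)
  f1 <- fit_longterm(s, constants = kinetic_params(gamma = 50))
  f2 <- fit_longterm(s, constants = kinetic_params(gamma = 100))
  expect_equal(f2$estimate$n0, f1$estimate$n0 / 2, tolerance = 1e-6)
  expect_equal(f2$estimate$beta, f1$estimate$beta, tolerance = 1e-6)
})

test_that("condition-specific gamma refits record and use the mapped rate", {
  p <- kinetic_params(n0 = 5e5, beta = 0.005)
  s <- make_igg_series(p, c(21, 30, 60, 90, 180, 365), condition = "hIL6")
  gmap <- c(control = 50, hIL6 = 100)
  f <- refit_with_condition_gamma(s, gmap)
  expect_equal(f$fixed$gamma, 100)
  expect_equal(f$estimate$n0, 2.5e5, tolerance = 1e-4) # half of truth at 2x gamma
  # matching single-condition map equals plain fit_longterm
  f_plain <- fit_longterm(s)
  f_same <- refit_with_condition_gamma(s, c(hIL6 = 50))
  expect_equal(f_same$estimate$n0, f_plain$estimate$n0)
  expect_equal(f_same$estimate$beta, f_plain$estimate$beta)
  expect_error(refit_with_condition_gamma(s, c(control = 50)), "condition")
  expect_error(refit_with_condition_gamma(s, c(hIL6 = 0)), "positive")
})

test_that("projection evaluates the fitted decay curve with guards", {
  p <- kinetic_params(n0 = 5e5, beta = 0.005)
  f <- fit_longterm(make_igg_series(p, c(21, 30, 60, 90, 180, 365)))
  expect_equal(project_count(f, 0), f$estimate$n0)
  expect_equal(project_count(f, 365), 8.06e4, tolerance = 1e-2)
  expect_warning(project_count(f, 500), "extrapolation")
  # beta = 0 projects a constant population
  f0 <- fit_longterm(make_igg_series(kinetic_params(n0 = 1e5, beta = 0),
                                     c(30, 90, 180, 365)))
  expect_equal(project_count(f0, c(0, 100, 365)),
               rep(f0$estimate$n0, 3), tolerance = 1e-4)
  # an unconverged fit refuses to project
  f_bad <- f
  f_bad$converged <- FALSE
  expect_error(project_count(f_bad, 10), "converge")
})

test_that("fit results flatten to the per-subject CSV shape", {
  p <- kinetic_params(n0 = 5e5, beta = 0.005)
  f1 <- fit_longterm(make_igg_series(p, c(21, 60, 180, 365)))
  f2 <- suppressWarnings(fit_biphasic_decay(
    simulate_decay_counts(noise_sigma_log = 0, seed = 1)))
  df <- fits_to_data_frame(list(a = f1, b = f2),
                           conditions = c("control", "vehicle"))
  expect_equal(nrow(df), 2)
  expect_equal(df$subject, c("a", "b"))
  expect_false(is.na(df$n0[1]))
  expect_true(is.na(df$n0[2]))
  expect_false(is.na(df$beta0[2]))
  expect_true(all(c("rss", "n_obs", "converged", "route") %in% names(df)))
})
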