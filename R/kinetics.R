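#' Kinetic parameters of the long-term engraftment model
#'
#' Bundles the constants and unknowns of the coupled plasma-cell /
#' antibody model: an engrafted PC population decaying at per-capita rate
#' `beta` secretes IgG at `gamma` pg/cell/day into a plasma pool of volume
#' `plasma_volume` mL, from which IgG is cleared at first-order rate `lam`.
#'
#' `gamma` and `lam` are normally fixed from the literature (the default
#' clearance corresponds to a ~7-day serum IgG half-life in the mouse);
#' `n0` and `beta` are the per-subject unknowns estimated by
#' [fit_longterm()].
#'
#' @param n0 Initial number of long-lived PCs retained at engraftment
#'   (cells). Must be >= 0.
#' @param beta PC decay rate (1/day). Must be >= 0.
#' @param gamma Per-cell IgG secretion rate (pg/cell/day). Must be >= 0.
#' @param lam First-order serum IgG clearance rate (1/day). Must be > 0.
#' @param plasma_volume Distribution volume converting secreted amount to
#'   serum concentration (mL). Must be > 0.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params(n0 = 5e5, beta = 0.005)
#' half_life(p$beta)
#' @export
kinetic_params <- function(n0 = NA_real_, beta = NA_real_, gamma = 50,
                           lam = log(2) / 7, plasma_volume = 1.5) {
  stopifnot(is.numeric(gamma), is.numeric(lam), is.numeric(plasma_volume))
  if (!is.na(n0) && n0 < 0) stop("n0 must be nonnegative")
  if (!is.na(beta) && beta < 0) stop("beta must be nonnegative")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (lam <= 0) stop("lam must be positive")
  if (plasma_volume <= 0) stop("plasma_volume must be positive")
  structure(
    list(n0 = as.numeric(n0), beta = as.numeric(beta),
         gamma = as.numeric(gamma), lam = as.numeric(lam),
         plasma_volume = as.numeric(plasma_volume)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Long-term PC kinetic parameters\n")
  cat(sprintf("  n0:    %g cells\n", x$n0))
  cat(sprintf("  beta:  %g /day (half-life %.1f days)\n", x$beta,
              if (!is.na(x$beta) && x$beta > 0) half_life(x$beta) else NA))
  cat(sprintf("  gamma: %g pg/cell/day\n", x$gamma))
  cat(sprintf("  lam:   %g /day\n", x$lam))
  cat(sprintf("  plasma volume: %g mL\n", x$plasma_volume))
  invisible(x)
}

#' Biphasic decay parameters
#'
#' Parameters of the time-dependent survival model
#' `N(t)/N0 = exp(-(beta0 * t + beta1 * t^2))` used for short-term ex vivo
#' cultures. The instantaneous per-capita decay rate is the derivative of
#' the exponent, `beta0 + 2 * beta1 * t`: `beta0` is the acute (day-0)
#' rate and `beta1 < 0` means the loss rate decelerates over the culture.
#'
#' If the instantaneous rate goes negative anywhere in `[0, window_end]`
#' the model implies regrowth inside its own validity window; the
#' constructor flags this (`rate_nonneg = FALSE`) and warns rather than
#' refusing, since fitted parameters near the boundary can cross it.
#'
#' @param beta0 Initial decay rate (1/day).
#' @param beta1 Decay-rate curvature coefficient (1/day^2); negative for
#'   decelerating loss.
#' @param window_end Last day of validity of the fit (day); default 21,
#'   the length of the standard culture.
#'
#' @return An object of class `biphasic_params` with a `rate_nonneg`
#'   validity flag.
#' @examples
#' bp <- biphasic_params(beta0 = 0.25, beta1 = -0.0058)
#' biphasic_survival(c(0, 6, 21), bp)
#' @export
biphasic_params <- function(beta0, beta1, window_end = 21) {
  stopifnot(is.numeric(beta0), is.numeric(beta1), length(beta0) == 1,
            length(beta1) == 1, is.finite(beta0), is.finite(beta1),
            window_end > 0)
  # rate beta0 + 2*beta1*t is linear: check only the endpoints
  rates <- beta0 + 2 * beta1 * c(0, window_end)
  ok <- all(rates >= 0)
  if (!ok) {
    warning(sprintf(
      "instantaneous decay rate is negative within [0, %g]: model implies regrowth inside its validity window",
      window_end), call. = FALSE)
  }
  structure(
    list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
         window_end = as.numeric(window_end), rate_nonneg = ok),
    class = "biphasic_params"
  )
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat("Biphasic decay parameters\n")
  cat(sprintf("  beta0: %g /day\n", x$beta0))
  cat(sprintf("  beta1: %g /day^2\n", x$beta1))
  cat(sprintf("  valid on [0, %g] days (rate nonnegative: %s)\n",
              x$window_end, x$rate_nonneg))
  invisible(x)
}

#' Plasma-cell count under constant exponential decay
#'
#' Evaluates `N(t) = n0 * exp(-beta * t)`, the solution of
#' `dN/dt = -beta * N`.
#'
#' @param t Time since transfer (days); vectorised, must be >= 0.
#' @param params A [kinetic_params()] object with `n0` and `beta` set.
#' @return Cell count(s), same length as `t`.
#' @examples
#' pc_count(365, kinetic_params(n0 = 5e5, beta = 0.005))
#' @export
pc_count <- function(t, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  params$n0 * exp(-params$beta * t)
}

#' Total antibody amount under the production-clearance model
#'
#' Closed-form solution of the one-compartment model: an exponentially
#' decaying PC population secretes IgG at `gamma` pg/cell/day while serum
#' IgG is cleared at rate `lam`, giving
#' `G(t) = gamma * n0 / (lam - beta) * (exp(-beta*t) - exp(-lam*t))` pg.
#' At the removable singularity `lam == beta` the limit form
#' `gamma * n0 * t * exp(-beta*t)` is used; the switch happens when
#' `|lam - beta| < 1e-8 * max(lam, beta)` to avoid catastrophic
#' cancellation.
#'
#' @inheritParams pc_count
#' @return Antibody amount(s) in pg.
#' @seealso [igg_concentration()] for the serum-concentration bridge used
#'   in fitting, [peak_time()] for the analytic maximiser.
#' @examples
#' p <- kinetic_params(n0 = 5e5, beta = 0.005)
#' antibody_amount(c(7, 14, 60), p)
#' @export
antibody_amount <- function(t, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  beta <- params$beta
  lam <- params$lam
  if (abs(lam - beta) < 1e-8 * max(lam, beta)) {
    params$gamma * params$n0 * t * exp(-beta * t)
  } else {
    params$gamma * params$n0 / (lam - beta) * (exp(-beta * t) - exp(-lam * t))
  }
}

#' Model-predicted serum IgG concentration
#'
#' Converts the antibody amount (pg) to a serum concentration (ng/mL) by
#' dividing by the plasma distribution volume (mL) and the pg-to-ng factor
#' 1000. This is the quantity fitted against ELISA time series; keeping
#' the volume explicit keeps the fitted `n0` in interpretable cell units.
#'
#' @inheritParams pc_count
#' @return Concentration(s) in ng/mL.
#' @export
igg_concentration <- function(t, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$plasma_volume <= 0) stop("plasma_volume must be positive")
  antibody_amount(t, params) / params$plasma_volume / 1000
}

#' Right-hand side of the coupled PC/antibody ODE system
#'
#' Returns `(dN/dt, dG/dt) = (-beta*N, gamma*N - lam*G)`. Exposed so the
#' closed form can be cross-checked against direct numerical integration.
#'
#' @param state Numeric vector `c(N, G)`: PC count (cells) and antibody
#'   amount (pg), both >= 0.
#' @param params A [kinetic_params()] object.
#' @return Numeric vector `c(dN, dG)`.
#' @export
ode_rhs <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"), length(state) == 2)
  if (any(state < 0)) stop("state must be nonnegative")
  N <- state[[1]]
  G <- state[[2]]
  c(-params$beta * N, params$gamma * N - params$lam * G)
}

#' Time of peak antibody amount
#'
#' Analytic maximiser of the closed-form antibody curve:
#' `ln(lam/beta)/(lam - beta)`, with limit `1/beta` as `lam -> beta`.
#' The formula is symmetric in its two arguments.
#'
#' @param beta PC decay rate (1/day), > 0.
#' @param lam IgG clearance rate (1/day), > 0.
#' @return Peak time in days.
#' @examples
#' peak_time(0.005, log(2) / 7) # ~31 days at default clearance
#' @export
peak_time <- function(beta, lam) {
  if (beta <= 0 || lam <= 0) stop("beta and lam must be positive")
  if (abs(lam - beta) < 1e-8 * max(lam, beta)) {
    1 / beta
  } else {
    log(lam / beta) / (lam - beta)
  }
}

#' Half-life implied by a first-order decay rate
#'
#' @param beta Decay rate (1/day), > 0.
#' @return Half-life in days, `log(2)/beta`.
#' @examples
#' half_life(0.005) # ~138.6 days
#' @export
half_life <- function(beta) {
  if (any(beta <= 0)) stop("beta must be positive")
  log(2) / beta
}

#' Surviving fraction under the biphasic decay model
#'
#' Evaluates `exp(-(beta0 * t + beta1 * t^2))`. Reduces to the single
#' exponential when `beta1 = 0`. Times outside `[0, window_end]` are an
#' extrapolation beyond the fitted window; the value is still computed
#' but a warning is attached.
#'
#' @param t Time since start of culture (days); vectorised.
#' @param params A [biphasic_params()] object.
#' @return Surviving fraction(s) in (0, 1] for valid parameters.
#' @export
biphasic_survival <- function(t, params) {
  stopifnot(inherits(params, "biphasic_params"))
  if (any(t < 0) || any(t > params$window_end)) {
    warning(sprintf("t outside fitted window [0, %g]: extrapolated values",
                    params$window_end), call. = FALSE)
  }
  exp(-(params$beta0 * t + params$beta1 * t^2))
}

#' Instantaneous per-capita decay rate of the biphasic model
#'
#' The derivative of the biphasic exponent: `beta0 + 2 * beta1 * t`.
#' At `t = 0` this equals `beta0`, the acute decay rate.
#'
#' @param t Time (days), >= 0; vectorised.
#' @param params A [biphasic_params()] object.
#' @return Rate(s) in 1/day.
#' @export
instantaneous_decay_rate <- function(t, params) {
  stopifnot(inherits(params, "biphasic_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  params$beta0 + 2 * params$beta1 * t
}
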