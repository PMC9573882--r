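#' Specification of a synthetic engraftment cohort
#'
#' Describes the cohort the generator emulates: per-condition subject
#' counts and mean engraftment parameters, lognormal between-subject
#' spread, the fixed kinetic constants, a bleed schedule, and a
#' multiplicative observation-noise scale. The defaults describe the
#' reference two-arm study: a control arm and an hIL-6 arm with ~3-fold
#' higher initial engrafted PC number but the same decay rate, arm sizes
#' of 7 and 8 animals, bleeds every 1-2 weeks to day 60 then sparser to
#' day 365, and 20% multiplicative ELISA noise.
#'
#' @param conditions Data frame with columns `condition`, `n_subjects`,
#'   `n0_mean` (cells) and `beta_mean` (1/day), one row per arm.
#' @param n0_sigma_log Between-subject lognormal sd of `n0` (log scale).
#' @param beta_sigma_log Between-subject lognormal sd of `beta`.
#' @param gamma,lam,plasma_volume Fixed kinetic constants shared by all
#'   subjects (see [kinetic_params()]).
#' @param sampling_days Bleed schedule (days, sorted, nonnegative).
#' @param noise_sigma_log Multiplicative observation-noise scale
#'   (lognormal sd on the log scale); 0 gives noiseless series.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(seed = 42)
#' cohort <- simulate_igg_series(spec)
#' length(cohort)
#' @export
cohort_spec <- function(conditions = data.frame(
                          condition = c("control", "hIL6"),
                          n_subjects = c(7L, 8L),
                          n0_mean = c(1.7e5, 5e5),
                          beta_mean = c(0.005, 0.005)),
                        n0_sigma_log = 0.3, beta_sigma_log = 0.15,
                        gamma = 50, lam = log(2) / 7, plasma_volume = 1.5,
                        sampling_days = c(7, 14, 21, 28, 42, 60, 90, 120,
                                          180, 270, 365),
                        noise_sigma_log = 0.2, seed = 1L) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "n_subjects", "n0_mean", "beta_mean") %in%
                  names(conditions)),
            nrow(conditions) >= 1)
  if (any(conditions$n_subjects < 1)) stop("n_subjects must be >= 1")
  if (any(conditions$n0_mean <= 0) || any(conditions$beta_mean < 0)) {
    stop("n0_mean must be positive and beta_mean nonnegative")
  }
  if (length(sampling_days) < 1 || any(sampling_days < 0) ||
      is.unsorted(sampling_days, strictly = TRUE)) {
    stop("sampling_days must be nonempty, nonnegative and strictly increasing")
  }
  if (n0_sigma_log < 0 || beta_sigma_log < 0 || noise_sigma_log < 0) {
    stop("sigma parameters must be nonnegative")
  }
  structure(
    list(conditions = conditions, n0_sigma_log = n0_sigma_log,
         beta_sigma_log = beta_sigma_log, gamma = gamma, lam = lam,
         plasma_volume = plasma_volume, sampling_days = sampling_days,
         noise_sigma_log = noise_sigma_log, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Lognormal draws with a given arithmetic mean: meanlog = log(m) - s^2/2.
rlnorm_mean <- function(n, mean, sigma_log) {
  if (sigma_log == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = log(mean) - sigma_log^2 / 2, sdlog = sigma_log)
}

#' Simulate a cohort of serum IgG time series
#'
#' Forward-simulates the closed-form antibody model: for each subject,
#' per-subject `(n0, beta)` are drawn lognormally around the arm means,
#' the concentration curve is evaluated on the bleed schedule, and each
#' observation is multiplied by lognormal noise `exp(eps)`,
#' `eps ~ N(0, noise_sigma_log^2)`. The generator is a pure function of
#' `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [time_series()] (kind `igg_concentration`), one per
#'   subject, with the per-subject true parameters attached as the
#'   `"truth"` attribute (a data frame with subject, condition, n0,
#'   beta).
#' @export
simulate_igg_series <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  series <- list()
  truth <- list()
  days <- spec$sampling_days
  for (i in seq_len(nrow(spec$conditions))) {
    cond <- spec$conditions$condition[i]
    n <- spec$conditions$n_subjects[i]
    n0s <- rlnorm_mean(n, spec$conditions$n0_mean[i], spec$n0_sigma_log)
    betas <- rlnorm_mean(n, spec$conditions$beta_mean[i], spec$beta_sigma_log)
    for (j in seq_len(n)) {
      p <- kinetic_params(n0 = n0s[j], beta = betas[j], gamma = spec$gamma,
                          lam = spec$lam, plasma_volume = spec$plasma_volume)
      y <- igg_concentration(days, p)
      if (spec$noise_sigma_log > 0) {
        y <- y * exp(stats::rnorm(length(days), 0, spec$noise_sigma_log))
      }
      id <- sprintf("%s_%02d", cond, j)
      series[[id]] <- time_series(id, cond, days, y, "igg_concentration")
      truth[[id]] <- data.frame(subject = id, condition = cond,
                                n0 = n0s[j], beta = betas[j],
                                stringsAsFactors = FALSE)
    }
  }
  attr(series, "truth") <- do.call(rbind, unname(truth))
  series
}

#' Simulate an ex vivo viable-count decay series
#'
#' Emulates a 21-day post-differentiation culture: counts follow the
#' biphasic survival curve (rapid loss over the first ~6 days, then
#' stabilisation) times multiplicative lognormal noise, rounded to whole
#' cells with a floor of zero. Defaults correspond to the vehicle
#' condition; pass the hIL-6 coefficients to simulate the treated arm.
#'
#' @param beta0 Initial decay rate (1/day).
#' @param beta1 Curvature coefficient (1/day^2).
#' @param n0_cells Seeded cell count at day 0.
#' @param sampling_days Count days within the culture window.
#' @param noise_sigma_log Multiplicative noise scale (0 = noiseless).
#' @param seed Integer seed.
#' @param subject_id,condition Labels for the returned series.
#' @return A [time_series()] of kind `cell_count`.
#' @examples
#' simulate_decay_counts(beta0 = 0.25, beta1 = -0.0058, seed = 7)
#' @export
simulate_decay_counts <- function(beta0 = 0.25, beta1 = -0.0058,
                                  n0_cells = 1e4,
                                  sampling_days = c(0, 2, 4, 6, 10, 14, 21),
                                  noise_sigma_log = 0.1, seed = 1L,
                                  subject_id = "replicate_1",
                                  condition = "vehicle") {
  stopifnot(n0_cells > 0, length(sampling_days) >= 1,
            all(sampling_days >= 0), noise_sigma_log >= 0)
  set.seed(as.integer(seed))
  bp <- biphasic_params(beta0, beta1, window_end = max(sampling_days, 1))
  counts <- n0_cells * biphasic_survival(sampling_days, bp)
  if (noise_sigma_log > 0) {
    counts <- counts * exp(stats::rnorm(length(counts), 0, noise_sigma_log))
  }
  counts <- pmax(round(counts), 0)
  time_series(subject_id, condition, sampling_days, counts, "cell_count")
}

#' Simulate an ELISPOT spot-size sample
#'
#' Draws per-spot sizes from a lognormal with a given arithmetic mean.
#' The default log-sd of 0.59 makes the central 95% of spot sizes span
#' roughly tenfold (`exp(2 * 1.96 * 0.59) ~ 10`), matching the observed
#' heterogeneity in per-cell secretion between antibody-secreting cells.
#'
#' @param n_spots Number of spots (>= 1).
#' @param mean_size Arithmetic mean spot size (> 0, arbitrary units).
#' @param sigma_log Lognormal sd on the log scale.
#' @param seed Integer seed.
#' @param subject_id,condition Labels for the returned sample.
#' @return A [spot_size_sample()].
#' @export
simulate_spot_sizes <- function(n_spots, mean_size = 100, sigma_log = 0.59,
                                seed = 1L, subject_id = "donor_1",
                                condition = "vehicle") {
  stopifnot(n_spots >= 1, mean_size > 0, sigma_log >= 0)
  set.seed(as.integer(seed))
  sizes <- rlnorm_mean(n_spots, mean_size, sigma_log)
  spot_size_sample(subject_id, condition, sizes)
}
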