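new_group_comparison <- function(statistic, p_value, test_name, sidedness,
                                 n_a, n_b, df = NA_real_) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         test_name = test_name, sidedness = sidedness,
         n_a = n_a, n_b = n_b, df = unname(df)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s-sided)\n", x$test_name, x$sidedness))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g (n = %d vs %d)\n",
              x$statistic, x$df, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

check_group <- function(x, name) {
  if (length(x) < 2 || any(!is.finite(x))) {
    stop(sprintf("group %s must have >= 2 finite values", name))
  }
}

#' Trapezoidal area under a subject's curve
#'
#' Integrates a measurement-versus-time curve by the trapezoid rule, the
#' standard per-animal summary for comparing longitudinal antibody or
#' luminescence levels between arms. Exact for piecewise-linear data and
#' additive over contiguous sub-intervals; each subject is integrated
#' over its own observed schedule, with no interpolation to a common
#' grid.
#'
#' @param series A [time_series()], or a numeric vector of times when
#'   `values` is supplied.
#' @param values Optional numeric vector of values matching `series`
#'   given as times.
#' @return The area (value units x day).
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 1, 0)) # 1
#' @export
auc_trapezoid <- function(series, values = NULL) {
  if (inherits(series, "pc_timeseries")) {
    t <- series$times
    v <- series$values
  } else {
    t <- series
    v <- values
  }
  stopifnot(is.numeric(t), is.numeric(v), length(t) == length(v))
  if (length(t) < 2) stop("AUC needs >= 2 time points")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Welch's unequal-variance t test
#'
#' Two-sample t test with the Satterthwaite degrees-of-freedom
#' approximation, used to compare fitted per-subject parameters (n0,
#' beta) or per-subject AUCs between arms without assuming equal
#' variances.
#'
#' @param a,b Numeric vectors, each with >= 2 finite values.
#' @param sidedness `"two"` or `"one"`; one-sided direction is set by
#'   `alternative`.
#' @param alternative For `sidedness = "one"`, `"greater"` tests mean(a)
#'   > mean(b), `"less"` the reverse.
#' @return A `group_comparison` (statistic, p-value, df, sample sizes).
#' @examples
#' welch_t(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
#' @export
welch_t <- function(a, b, sidedness = c("two", "one"),
                    alternative = c("greater", "less")) {
  sidedness <- match.arg(sidedness)
  alternative <- match.arg(alternative)
  check_group(a, "a")
  check_group(b, "b")
  if (stats::var(a) + stats::var(b) == 0) {
    stop("both groups have zero variance; Welch statistic undefined")
  }
  alt <- if (sidedness == "two") "two.sided" else alternative
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = alt)
  new_group_comparison(tt$statistic, tt$p.value, "Welch two-sample t",
                       sidedness, length(a), length(b), tt$parameter)
}

#' Paired t test
#'
#' One-sample t test on within-pair differences, used for repeated
#' measurements on the same donors/replicates (e.g. vehicle vs hIL-6
#' cultures from the same donor at each time point).
#'
#' @inheritParams welch_t
#' @return A `group_comparison`.
#' @export
paired_t <- function(a, b, sidedness = c("two", "one"),
                     alternative = c("greater", "less")) {
  sidedness <- match.arg(sidedness)
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("paired test requires equal lengths")
  check_group(a, "a")
  check_group(b, "b")
  if (stats::var(a - b) == 0) {
    stop("within-pair differences have zero variance; t statistic undefined")
  }
  alt <- if (sidedness == "two") "two.sided" else alternative
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alt)
  new_group_comparison(tt$statistic, tt$p.value, "paired t", sidedness,
                       length(a), length(b), tt$parameter)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return The correlation `r` in `[-1, 1]`, with the two-sided test
#'   p-value attached as attribute `"p_value"`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1) # exactly 1
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(unname(ct$estimate), p_value = ct$p.value)
}

#' Min-max normalization to [0, 1]
#'
#' Rescales a vector affinely so its minimum maps to 0 and maximum to 1,
#' as used to put per-replicate intensity or flux measurements on a
#' common scale. Invariant under positive affine transforms of the
#' input and idempotent on already-normalized data.
#'
#' @param values Numeric vector with >= 2 values and `max > min`.
#' @return Rescaled vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2) stop("need >= 2 values")
  rng <- range(values)
  if (rng[1] == rng[2]) stop("max equals min; normalization undefined")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Per-time-point mean and confidence band across subjects
#'
#' For each time point observed by at least two subjects, computes the
#' across-subject mean and a t-based confidence interval of the mean
#' (the "solid line and shadow" summary of longitudinal cohort plots).
#' Time points observed by fewer than two subjects are dropped with a
#' notice.
#'
#' @param group List of [time_series()] objects from one arm.
#' @param level Confidence level in `[0, 1)`; `level = 0` collapses the
#'   band to the mean.
#' @return Data frame with columns `day`, `n`, `mean`, `lo`, `hi`.
#' @export
mean_ci_band <- function(group, level = 0.95) {
  stopifnot(is.list(group), length(group) >= 2,
            all(vapply(group, inherits, logical(1), "pc_timeseries")),
            level >= 0, level < 1)
  long <- do.call(rbind, lapply(group, as.data.frame))
  days <- sort(unique(long$day))
  rows <- lapply(days, function(d) {
    v <- long$value[long$day == d]
    if (length(v) < 2) return(NULL)
    m <- mean(v)
    half <- if (level == 0) 0 else {
      stats::qt((1 + level) / 2, df = length(v) - 1) *
        stats::sd(v) / sqrt(length(v))
    }
    data.frame(day = d, n = length(v), mean = m, lo = m - half, hi = m + half)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    message(sprintf("mean_ci_band: dropped %d time point(s) with < 2 subjects",
                    dropped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no time point is shared by >= 2 subjects")
  out
}

#' Holm adjustment helper for per-time-point p-values
#'
#' Per-time-point paired testing across a schedule is reported
#' unadjusted by default (one star per time point); this helper applies
#' the Holm step-down correction when family-wise control is wanted.
#'
#' @param p Numeric vector of p-values.
#' @return Holm-adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
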