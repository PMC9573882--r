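#' One subject's longitudinal measurement series
#'
#' Container for a single subject's measurements over time: serum IgG
#' concentrations (ng/mL), viable cell counts, or normalized luminescence
#' flux. Times must be unique once sorted (duplicate-day handling is a
#' reader policy, see [read_timeseries_csv()]), nonnegative and are stored
#' in increasing order; values must be nonnegative.
#'
#' @param subject_id Subject label.
#' @param condition Condition label (e.g. `"control"`, `"hIL6"`).
#' @param times Numeric days since transfer / start of culture, >= 0.
#'   Fractional days are allowed.
#' @param values Nonnegative measurements, same length as `times`.
#' @param value_kind One of `"igg_concentration"` (ng/mL), `"cell_count"`
#'   (cells), `"luminescence"` (normalized flux).
#' @return An object of class `pc_timeseries`.
#' @examples
#' time_series("m1", "control", c(7, 14, 21), c(900, 2400, 2100))
#' @export
time_series <- function(subject_id, condition, times, values,
                        value_kind = c("igg_concentration", "cell_count",
                                       "luminescence")) {
  value_kind <- match.arg(value_kind)
  stopifnot(length(subject_id) == 1, length(condition) == 1,
            is.numeric(times), is.numeric(values))
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and nonnegative")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and nonnegative")
  }
  o <- order(times)
  times <- times[o]
  values <- values[o]
  if (anyDuplicated(times)) {
    stop("duplicate times; average duplicates before constructing ",
         "(read_timeseries_csv does this)")
  }
  structure(
    list(subject_id = as.character(subject_id),
         condition = as.character(condition),
         times = as.numeric(times), values = as.numeric(values),
         value_kind = value_kind),
    class = "pc_timeseries"
  )
}

#' @export
print.pc_timeseries <- function(x, ...) {
  cat(sprintf("<pc_timeseries> subject %s (%s), %d points of %s on days %g-%g\n",
              x$subject_id, x$condition, length(x$times), x$value_kind,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.pc_timeseries <- function(x, ...) {
  data.frame(subject = x$subject_id, condition = x$condition,
             day = x$times, value = x$values, kind = x$value_kind,
             stringsAsFactors = FALSE)
}

#' ELISPOT spot-size sample for one subject
#'
#' Holds the vector of per-spot sizes (an opaque positive scalar derived
#' from three-dimensional pixel quantification) for one subject and
#' condition.
#'
#' @param subject_id Subject label.
#' @param condition Condition label.
#' @param sizes Nonempty vector of positive spot sizes.
#' @return An object of class `spot_size_sample`.
#' @export
spot_size_sample <- function(subject_id, condition, sizes) {
  stopifnot(length(subject_id) == 1, length(condition) == 1,
            is.numeric(sizes))
  if (length(sizes) < 1) stop("sizes must be nonempty")
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("all spot sizes must be finite and positive")
  }
  structure(
    list(subject_id = as.character(subject_id),
         condition = as.character(condition), sizes = as.numeric(sizes)),
    class = "spot_size_sample"
  )
}

#' @export
print.spot_size_sample <- function(x, ...) {
  cat(sprintf("<spot_size_sample> subject %s (%s), %d spots, mean size %.3g\n",
              x$subject_id, x$condition, length(x$sizes), mean(x$sizes)))
  invisible(x)
}
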