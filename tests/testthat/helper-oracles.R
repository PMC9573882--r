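# Independent reference computations used to check the statistics wrappers.
# Deliberately written from the textbook formulas, not via stats::t.test.

welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

paired_oracle <- function(a, b) {
  d <- a - b
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  df <- length(d) - 1
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Noiseless model series on a given schedule.
make_igg_series <- function(params, days, id = "s1", condition = "control") {
  time_series(id, condition, days, igg_concentration(days, params),
              "igg_concentration")
}
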