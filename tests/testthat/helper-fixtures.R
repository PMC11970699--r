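# Small in-code fixtures shared across test files.

# A three-row design whose leave-one-out fits are exactly determined
# 2x2 systems, so jackknife totals can be solved by hand.
three_row_design <- function() {
  structure(
    data.frame(
      camp_name = c("alpha", "beta", "gamma"),
      person_time = c(2, 1.5, 1),
      monsoon_fraction = c(0, 1, 0.5),
      x_b = c(2, 0, 1),
      x_m = c(0, 1.5, 0.5),
      deaths = c(250, 600, 400),
      stringsAsFactors = FALSE
    ),
    class = c("camp_design", "data.frame")
  )
}

# A noiseless design: deaths are exactly b * x_b + m * x_m.
noiseless_design <- function(b = 100, m = 300) {
  x_b <- c(5, 0, 2, 1, 0, 3)
  x_m <- c(0, 2, 1, 0.5, 4, 0)
  data.frame(x_b = x_b, x_m = x_m, deaths = b * x_b + m * x_m)
}

# One-row camp table matching the Salt Lake general-deaths record.
salt_lake_csv <- function(path) {
  writeLines(c(
    "camp_name,state,population,deaths,start_date,end_date,cause_class,official_source,source_note",
    "Salt Lake,West Bengal,170000,3671,1971-07-01,1971-11-30,general,FALSE,survey"
  ), path)
  path
}

# Daily-step Riemann oracle for the influx person-time integral:
# midpoint value of the piecewise-linear curve summed over unit days.
daily_step_person_time <- function(series, window = NULL) {
  t <- as.numeric(series$date)
  lo <- if (is.null(window)) t[1] else as.numeric(as.Date(window[1]))
  hi <- if (is.null(window)) t[length(t)] else as.numeric(as.Date(window[2]))
  days <- seq(lo, hi - 1)
  vals <- stats::approx(t, series$cumulative, xout = days + 0.5)$y
  sum(vals) / 1e6
}

# Closed-form no-intercept least squares (normal equations oracle).
ols_oracle <- function(design) {
  X <- cbind(design$x_b, design$x_m)
  drop(solve(crossprod(X), crossprod(X, design$deaths)))
}
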