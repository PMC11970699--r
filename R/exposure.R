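#' Inclusive duration of a calendar interval, in days
#'
#' Day counts are inclusive of both endpoints (`end - start + 1`), the
#' convention that reproduces every printed duration in the bundled camp
#' table (e.g. July 1 - November 30 is 153 days).
#'
#' @param start,end `Date` vectors (or ISO 8601 strings), `end >= start`.
#' @return Integer day counts.
#' @export
#' @examples
#' duration_days("1971-07-01", "1971-11-30") # 153
duration_days <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("duration_days: unparsable date", call. = FALSE)
  }
  if (any(end < start)) {
    stop("duration_days: end date precedes start date", call. = FALSE)
  }
  as.integer(end - start) + 1L
}

#' Fraction of a record's duration exposed to the monsoon-excess rate
#'
#' For `cause_class == "all"` records this is the overlap of the record
#' interval with the monsoon window divided by the record duration.
#' Under `overlap_convention = "inclusive"` both counts are inclusive
#' day counts; under `"paper"` the overlap is a plain date difference
#' (duration-style subtraction) while the total stays inclusive, which
#' reproduces the printed 121/199 = 0.608 fraction for the Banjetia and
#' Lalbagh record.
#'
#' The cause label, not the calendar, assigns the hazard: `"general"`
#' records return 0 and `"monsoon_excess"` records return 1 even when
#' their interval lies outside the monsoon window (e.g. the Jambu Island
#' cyclone record).
#'
#' @param records A `camp_records` data frame.
#' @param config A [study_config()].
#' @return Numeric vector of fractions in `[0, 1]`, one per record.
#' @export
monsoon_fraction <- function(records, config = study_config()) {
  records <- as_camp_records(records)
  n <- nrow(records)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cls <- records$cause_class[i]
    if (cls == "general") {
      out[i] <- 0
    } else if (cls == "monsoon_excess") {
      out[i] <- 1
    } else {
      lo <- max(records$start_date[i], config$monsoon_start)
      hi <- min(records$end_date[i], config$monsoon_end)
      total <- duration_days(records$start_date[i], records$end_date[i])
      overlap <- if (hi < lo) {
        0
      } else if (config$overlap_convention == "inclusive") {
        as.numeric(hi - lo) + 1
      } else {
        as.numeric(hi - lo)
      }
      out[i] <- overlap / total
    }
  }
  out
}

#' Build the regression design from camp records
#'
#' Each record contributes one equation of the linear model
#' `deaths = b * x_b + m * x_m`, where `x_b` and `x_m` are the million
#' person-days exposed to the baseline and monsoon-excess rates:
#'
#' * `person_time = population * duration_days / 1e6`;
#' * `"general"`: `(x_b, x_m) = (person_time, 0)`;
#' * `"monsoon_excess"`: `(0, person_time)`;
#' * `"all"`: `(person_time, person_time * monsoon_fraction)`.
#'
#' @param records A `camp_records` data frame.
#' @param config A [study_config()].
#' @return A `camp_design` data frame with columns `camp_name`,
#'   `person_time`, `monsoon_fraction`, `x_b`, `x_m`, `deaths`.
#' @export
#' @examples
#' design <- build_design(refugee_camps_1971())
#' design[1, ] # Salt Lake general: person_time 26.01, x_b 26.01, x_m 0
build_design <- function(records, config = study_config()) {
  records <- as_camp_records(records)
  dur <- duration_days(records$start_date, records$end_date)
  pt <- records$population * dur / 1e6
  frac <- monsoon_fraction(records, config)
  x_b <- ifelse(records$cause_class == "monsoon_excess", 0, pt)
  x_m <- ifelse(records$cause_class == "monsoon_excess", pt, pt * frac)
  out <- data.frame(
    camp_name = records$camp_name,
    person_time = pt,
    monsoon_fraction = frac,
    x_b = x_b,
    x_m = x_m,
    deaths = records$deaths,
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$x_b + out$x_m > 0))
  class(out) <- c("camp_design", "data.frame")
  out
}

#' Construct a cumulative refugee-influx series
#'
#' An influx series holds dated observations of the cumulative refugee
#' count in India (net influx: dates strictly increasing, counts
#' non-decreasing). Population-level person-time is obtained from it by
#' [person_time_from_influx()].
#'
#' @param dates `Date` vector (or ISO strings), strictly increasing.
#' @param cumulative Non-decreasing cumulative refugee counts.
#' @return An `influx_series` object.
#' @export
influx_series <- function(dates, cumulative) {
  dates <- as.Date(dates)
  cumulative <- as.numeric(cumulative)
  if (any(is.na(dates)) || any(is.na(cumulative))) {
    stop("influx_series: missing or unparsable values", call. = FALSE)
  }
  if (length(dates) != length(cumulative)) {
    stop("influx_series: dates and counts differ in length", call. = FALSE)
  }
  if (length(dates) >= 2 && any(diff(as.numeric(dates)) <= 0)) {
    stop("influx_series: dates must be strictly increasing", call. = FALSE)
  }
  if (any(diff(cumulative) < 0)) {
    stop("influx_series: cumulative counts must be non-decreasing",
         call. = FALSE)
  }
  structure(list(date = dates, cumulative = cumulative),
            class = "influx_series")
}

#' Read an influx series from a CSV file
#'
#' Expects columns `date` (ISO 8601) and `cumulative_refugees`.
#'
#' @param path Path to a CSV file.
#' @return An `influx_series` object.
#' @export
read_influx <- function(path) {
  if (!file.exists(path)) stop("influx file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "cumulative_refugees") %in% names(x))) {
    stop("influx file must have columns 'date' and 'cumulative_refugees'",
         call. = FALSE)
  }
  influx_series(x$date, x$cumulative_refugees)
}

#' Write an influx series to a CSV file
#'
#' @param series An `influx_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_influx <- function(series, path) {
  stopifnot(inherits(series, "influx_series"))
  utils::write.csv(
    data.frame(date = format(series$date, "%Y-%m-%d"),
               cumulative_refugees = series$cumulative),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Person-time under a cumulative influx curve
#'
#' Integrates the cumulative-count curve over a window, interpolating
#' piecewise-linearly between observations, and returns the result in
#' million person-days. This is the population-level analogue of the
#' per-camp `population * days` products: the area under the cumulative
#' influx curve is the total person-time spent by all refugees.
#'
#' @param series An [influx_series()] with at least 2 observations.
#' @param window Optional `Date` vector of length 2 bounding the
#'   integration; must lie within the observation span. `NULL` (default)
#'   integrates the full span.
#' @return Person-time in million person-days.
#' @export
#' @examples
#' s <- influx_series(c("1971-04-01", "1971-07-10"), c(1e6, 1e6))
#' person_time_from_influx(s) # 100 days at 1e6 persons -> 100
person_time_from_influx <- function(series, window = NULL) {
  stopifnot(inherits(series, "influx_series"))
  if (length(series$date) < 2) {
    stop("person_time_from_influx: need at least 2 observations",
         call. = FALSE)
  }
  t <- as.numeric(series$date)
  y <- series$cumulative
  if (is.null(window)) {
    lo <- t[1]
    hi <- t[length(t)]
  } else {
    window <- as.Date(window)
    if (length(window) != 2 || any(is.na(window))) {
      stop("person_time_from_influx: window must be two dates", call. = FALSE)
    }
    lo <- as.numeric(min(window))
    hi <- as.numeric(max(window))
    if (lo < t[1] || hi > t[length(t)]) {
      stop("person_time_from_influx: window outside observation span",
           call. = FALSE)
    }
  }
  if (hi <= lo) return(0)
  # Trapezoid integral of the piecewise-linear curve, clipped to window.
  interp <- function(q) stats::approx(t, y, xout = q)$y
  knots <- sort(unique(c(lo, hi, t[t > lo & t < hi])))
  vals <- interp(knots)
  sum(diff(knots) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2) / 1e6
}
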