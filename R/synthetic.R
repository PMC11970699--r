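#' Specification of a synthetic camp-record simulation
#'
#' Describes a forward simulation from the same binomial person-time
#' model the estimator assumes: each synthetic camp draws its death
#' count from `Binomial(population * days, rate / 1e6)` where the rate
#' (deaths per million person-days) is `true_b`, `true_m`, or
#' `true_b + monsoon_fraction * true_m` according to the camp's cause
#' class. Defaults mirror the bundled study table: 17 camps, rates near
#' the fitted study values, populations spanning the observed 3,000 -
#' 250,000 range, intervals within the April 10 - December 15 influx
#' window, and the observed cause-class mix (3 general, 9 monsoon-excess,
#' 5 all-cause out of 17).
#'
#' @param n_camps Number of synthetic camps.
#' @param true_b,true_m True baseline and monsoon-excess rates, deaths
#'   per million person-days.
#' @param population_range Integer range to draw camp populations from.
#' @param date_span Two dates bounding all camp intervals.
#' @param duration_range Integer range of interval lengths in days.
#' @param cause_mix Named proportions over
#'   `c("general", "monsoon_excess", "all")`; must sum to 1.
#' @param underreport_factor Divide simulated death counts by this
#'   (>= 1) before output, mimicking official undercounting; rows are
#'   flagged `official_source = TRUE` when the factor exceeds 1.
#' @param noiseless If `TRUE`, death counts are set to their (rounded)
#'   binomial expectations instead of being drawn — the deterministic
#'   limit used to check estimator bias. Exact only up to the integer
#'   rounding of each count.
#' @param seed Integer seed; simulation is reproducible given the seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_camps = 17,
                            true_b = 174,
                            true_m = 370,
                            population_range = c(3000, 250000),
                            date_span = c("1971-04-10", "1971-12-15"),
                            duration_range = c(5, 120),
                            cause_mix = c(general = 3 / 17,
                                          monsoon_excess = 9 / 17,
                                          all = 5 / 17),
                            underreport_factor = 1,
                            noiseless = FALSE,
                            seed = 1) {
  spec <- list(
    n_camps = as.integer(n_camps),
    true_b = as.numeric(true_b),
    true_m = as.numeric(true_m),
    population_range = as.integer(population_range),
    date_span = as.Date(date_span),
    duration_range = as.integer(duration_range),
    cause_mix = cause_mix,
    underreport_factor = as.numeric(underreport_factor),
    noiseless = isTRUE(noiseless),
    seed = as.integer(seed)
  )
  if (spec$n_camps < 2) stop("simulation_spec: need n_camps >= 2",
                             call. = FALSE)
  if (spec$true_b < 0 || spec$true_m < 0) {
    stop("simulation_spec: true rates must be non-negative", call. = FALSE)
  }
  if (!setequal(names(spec$cause_mix), cause_classes)) {
    stop("simulation_spec: cause_mix must be named over ",
         paste(cause_classes, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(spec$cause_mix) - 1) > 1e-8) {
    stop("simulation_spec: cause_mix proportions must sum to 1",
         call. = FALSE)
  }
  if (spec$underreport_factor < 1) {
    stop("simulation_spec: underreport_factor must be >= 1", call. = FALSE)
  }
  if (any(is.na(spec$date_span)) || spec$date_span[1] >= spec$date_span[2]) {
    stop("simulation_spec: invalid date_span", call. = FALSE)
  }
  class(spec) <- "simulation_spec"
  spec
}

#' Simulate camp records from the binomial person-time model
#'
#' Each synthetic camp draws a cause class, a population, and an
#' interval, then draws its death count from a single binomial with
#' index `population * days` (person-day trials) and the applicable
#' per-person-day death probability. When `underreport_factor > 1` the
#' drawn counts are divided by the factor and rounded, and the rows are
#' flagged as official sources, so the undercount-adjustment scenario
#' can be exercised against a known truth.
#'
#' @param spec A [simulation_spec()].
#' @param config A [study_config()]; supplies the monsoon window used
#'   for the mixed-exposure rate of all-cause camps.
#' @return A validated `camp_records` data frame with `spec$n_camps`
#'   rows.
#' @export
simulate_camps <- function(spec, config = study_config()) {
  stopifnot(inherits(spec, "simulation_spec"))
  p_max <- (spec$true_b + spec$true_m) / 1e6
  if (p_max >= 1) {
    stop("simulate_camps: per person-day death probability >= 1; implausible spec",
         call. = FALSE)
  }
  with_seed(spec$seed, {
    n <- spec$n_camps
    classes <- sample(cause_classes, n, replace = TRUE,
                      prob = spec$cause_mix[cause_classes])
    # Keep the design identifiable (also after any single leave-one-out
    # deletion) whenever the mix gives the needed classes positive
    # probability: ensure at least two rows loading on each rate.
    mix <- spec$cause_mix
    ensure_two <- function(classes, loading, filler) {
      deficit <- 2 - sum(classes %in% loading)
      if (deficit > 0 && sum(mix[loading]) > 0) {
        fill <- filler[which.max(mix[filler])]
        classes[which(!(classes %in% loading))[seq_len(deficit)]] <- fill
      }
      classes
    }
    classes <- ensure_two(classes, c("general", "all"), c("general", "all"))
    classes <- ensure_two(classes, c("monsoon_excess", "all"),
                          c("monsoon_excess", "all"))
    pop <- sample(spec$population_range[1]:spec$population_range[2], n,
                  replace = TRUE)
    dur <- sample(spec$duration_range[1]:spec$duration_range[2], n,
                  replace = TRUE)
    span_days <- as.integer(spec$date_span[2] - spec$date_span[1]) + 1L
    dur <- pmin(dur, span_days)
    start <- spec$date_span[1] +
      vapply(span_days - dur, function(slack) sample.int(slack + 1L, 1L) - 1L,
             integer(1))
    end <- start + dur - 1L
    recs <- data.frame(
      camp_name = sprintf("sim_camp_%02d", seq_len(n)),
      state = "synthetic",
      population = pop,
      deaths = 0L,
      start_date = start,
      end_date = end,
      cause_class = classes,
      official_source = spec$underreport_factor > 1,
      source_note = "synthetic binomial draw",
      stringsAsFactors = FALSE
    )
    frac <- monsoon_fraction(as_camp_records(recs), config)
    rate <- ifelse(classes == "general", spec$true_b,
                   ifelse(classes == "monsoon_excess", spec$true_m,
                          spec$true_b + frac * spec$true_m))
    person_days <- as.numeric(pop) * dur
    deaths <- if (spec$noiseless) {
      round_half_up(person_days * rate / 1e6)
    } else {
      rbinom(n, size = person_days, prob = rate / 1e6)
    }
    if (spec$underreport_factor > 1) {
      deaths <- round_half_up(deaths / spec$underreport_factor)
    }
    recs$deaths <- deaths
    as_camp_records(recs)
  })
}

#' Simulate a cumulative refugee-influx series
#'
#' Generates a monotone non-decreasing cumulative influx curve reaching
#' `total_refugees` at the end of `span`, emulating the wartime influx
#' records. Three shapes are available:
#'
#' * `"linear"`: a constant-rate ramp from 0 to the total;
#' * `"logistic"`: a smooth S-curve, pinned exactly to 0 and the total
#'   at the span endpoints;
#' * `"piecewise"`: a piecewise-linear curve calibrated in closed form
#'   so that its full-span person-time integral equals
#'   `config$pt_total` and its monsoon-window integral equals
#'   `config$pt_monsoon` (million person-days). Matching both printed
#'   aggregates with a monotone curve forces a front-loaded influx:
#'   a steep early ramp, a plateau before June, then a linear monsoon
#'   rise to the total.
#'
#' @param total_refugees Final cumulative count (default 9.9 million).
#' @param span Two dates bounding the series.
#' @param shape Curve shape, see above.
#' @param seed Optional seed; when given, extra observation dates are
#'   sampled inside the span (the curve itself is unchanged, since the
#'   shape knots are always retained).
#' @param config A [study_config()]; used by the `"piecewise"` shape.
#' @return An [influx_series()].
#' @export
simulate_influx <- function(total_refugees = 9.9e6,
                            span = c("1971-04-10", "1971-12-15"),
                            shape = c("linear", "logistic", "piecewise"),
                            seed = NULL,
                            config = study_config()) {
  shape <- match.arg(shape)
  span <- as.Date(span)
  if (any(is.na(span)) || span[1] >= span[2]) {
    stop("simulate_influx: invalid span", call. = FALSE)
  }
  if (total_refugees <= 0) {
    stop("simulate_influx: total_refugees must be positive", call. = FALSE)
  }
  t0 <- as.numeric(span[1])
  t1 <- as.numeric(span[2])
  L <- t1 - t0

  if (shape == "linear") {
    knots_t <- c(t0, t1)
    knots_y <- c(0, total_refugees)
  } else if (shape == "logistic") {
    mid <- (t0 + t1) / 2
    sc <- L / 10
    f <- function(t) stats::plogis((t - mid) / sc)
    knots_t <- seq(t0, t1, length.out = 41)
    knots_y <- total_refugees * (f(knots_t) - f(t0)) / (f(t1) - f(t0))
  } else {
    # Closed-form calibration against the two person-time aggregates.
    ms <- as.numeric(config$monsoon_start)
    me <- as.numeric(config$monsoon_end)
    if (ms <= t0 || me >= t1) {
      stop("simulate_influx: piecewise shape needs the monsoon window strictly inside the span",
           call. = FALSE)
    }
    ramp_end <- t0 + 5
    # Level a at monsoon start so the monsoon trapezoid hits pt_monsoon,
    # rising linearly to the total at monsoon end, flat afterwards.
    a <- 2 * config$pt_monsoon * 1e6 / (me - ms) - total_refugees
    post <- (t1 - me) * total_refugees
    pre_target <- config$pt_total * 1e6 - config$pt_monsoon * 1e6 - post
    # Pre-monsoon: ramp 0 -> h over 5 days, then linear h -> a by June.
    # Integral: 2.5 h + (ms - ramp_end) (h + a) / 2 = pre_target.
    h <- (pre_target - (ms - ramp_end) * a / 2) /
      ((ramp_end - t0) / 2 + (ms - ramp_end) / 2)
    if (is.na(a) || is.na(h) || h < 0 || h > a || a > total_refugees) {
      stop("simulate_influx: aggregates infeasible for a monotone piecewise curve over this span",
           call. = FALSE)
    }
    knots_t <- c(t0, ramp_end, ms, me, t1)
    knots_y <- c(0, h, a, total_refugees, total_refugees)
  }

  if (!is.null(seed)) {
    extra <- with_seed(seed, {
      interior <- setdiff(seq(t0 + 1, t1 - 1), round(knots_t))
      sort(sample(interior, min(20, length(interior))))
    })
    all_t <- sort(unique(c(knots_t, extra)))
    all_y <- stats::approx(knots_t, knots_y, xout = all_t)$y
  } else {
    all_t <- knots_t
    all_y <- knots_y
  }
  influx_series(as.Date(all_t, origin = "1970-01-01"), all_y)
}

#' Parameter-recovery and coverage experiment
#'
#' Runs the full estimation pipeline on `replicates` independent
#' synthetic datasets drawn from a [simulation_spec()] and summarises
#' how well the known truth is recovered: per-replicate estimates of
#' `b`, `m` and the excess toll, bias and RMSE of each, and the
#' empirical coverage of the excess-toll confidence interval. The true
#' excess toll is the model functional at the true rates,
#' `pt_total * true_b + pt_monsoon * true_m - natural_toll`.
#'
#' Replicate `i` uses seed `spec$seed + i - 1`.
#'
#' @param spec A [simulation_spec()].
#' @param replicates Number of replicates (>= 1).
#' @param config A [study_config()].
#' @return A `recovery_experiment` list: `results` (one row per
#'   replicate: `b`, `m`, `excess`, `ci_lower`, `ci_upper`, `covered`,
#'   `se_b`, `se_m`) and `summary` (truth, bias, RMSE, coverage).
#' @export
recovery_experiment <- function(spec, replicates, config = study_config()) {
  stopifnot(inherits(spec, "simulation_spec"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1) {
    stop("recovery_experiment: replicates must be >= 1", call. = FALSE)
  }
  truth_excess <- config$pt_total * spec$true_b +
    config$pt_monsoon * spec$true_m - natural_toll(config)$toll
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    rspec <- spec
    rspec$seed <- spec$seed + i - 1L
    camps <- simulate_camps(rspec, config)
    design <- build_design(camps, config)
    fit <- fit_rates(design, config)
    loo <- loo_variance(design, config)
    tolls <- excess_with_ci(fit, loo, config)
    rows[[i]] <- data.frame(
      replicate = i,
      b = fit$b,
      m = fit$m,
      excess = tolls$excess_toll,
      ci_lower = tolls$excess_ci[["lower"]],
      ci_upper = tolls$excess_ci[["upper"]],
      covered = tolls$excess_ci[["lower"]] <= truth_excess &&
        truth_excess <= tolls$excess_ci[["upper"]],
      se_b = loo$se_b,
      se_m = loo$se_m
    )
  }
  results <- do.call(rbind, rows)
  summary <- data.frame(
    truth_b = spec$true_b,
    truth_m = spec$true_m,
    truth_excess = truth_excess,
    bias_b = mean(results$b) - spec$true_b,
    rmse_b = sqrt(mean((results$b - spec$true_b)^2)),
    bias_m = mean(results$m) - spec$true_m,
    rmse_m = sqrt(mean((results$m - spec$true_m)^2)),
    bias_excess = mean(results$excess) - truth_excess,
    rmse_excess = sqrt(mean((results$excess - truth_excess)^2)),
    coverage = mean(results$covered)
  )
  structure(list(results = results, summary = summary, spec = spec),
            class = "recovery_experiment")
}
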