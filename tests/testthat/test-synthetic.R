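test_that("simulation is reproducible from its seed", {
  spec <- simulation_spec(seed = 7)
  a <- simulate_camps(spec)
  b <- simulate_camps(spec)
  expect_identical(a, b)
  c <- simulate_camps(simulation_spec(seed = 8))
  expect_false(identical(a$deaths, c$deaths))
  # simulation does not disturb the global RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_camps(spec))
  expect_identical(rnorm(1), before)
})

test_that("simulated records satisfy all camp-record invariants", {
  for (seed in 1:5) {
    camps <- simulate_camps(simulation_spec(seed = seed, n_camps = 25))
    expect_s3_class(camps, "camp_records") # construction validates
    expect_true(all(camps$deaths <= camps$population))
    expect_true(all(camps$start_date >= as.Date("1971-04-10")))
    expect_true(all(camps$end_date <= as.Date("1971-12-15")))
    expect_true(all(camps$cause_class %in%
                      c("general", "monsoon_excess", "all")))
  }
})

test_that("spec validation rejects inconsistent simulation settings", {
  expect_error(simulation_spec(cause_mix = c(general = 0.5,
                                             monsoon_excess = 0.2,
                                             all = 0.2)),
               "sum to 1")
  expect_error(simulation_spec(true_b = -1), "non-negative")
  expect_error(simulation_spec(underreport_factor = 0.5), ">= 1")
  expect_error(simulate_camps(simulation_spec(true_m = 2e6)), "implausible")
})

test_that("empirical death fractions converge to the specified rate", {
  # law of large numbers at population 1e7: the realised rate of a
  # general-cause camp is within 1% of the baseline truth
  spec <- simulation_spec(
    n_camps = 4, true_b = 174, true_m = 370,
    population_range = c(1e7, 1e7), duration_range = c(100, 100),
    cause_mix = c(general = 1, monsoon_excess = 0, all = 0), seed = 11
  )
  camps <- simulate_camps(spec)
  realised <- camp_rate(camps)
  expect_true(all(abs(realised - 174) / 174 < 0.01))
})

test_that("simulated influx curves honour shape contracts", {
  lin <- simulate_influx(9.9e6, c("1971-04-11", "1971-12-16"),
                         shape = "linear")
  # triangle: total * span / 2 person-days
  expect_equal(person_time_from_influx(lin), 9.9e6 * 249 / 2 / 1e6,
               tolerance = 1e-10)

  log_s <- simulate_influx(shape = "logistic", seed = 3)
  expect_true(all(diff(log_s$cumulative) >= 0))
  expect_equal(log_s$cumulative[1], 0)
  expect_equal(log_s$cumulative[length(log_s$cumulative)], 9.9e6)

  pw <- simulate_influx(shape = "piecewise")
  cfg <- study_config()
  expect_true(all(diff(pw$cumulative) >= 0))
  full <- person_time_from_influx(pw)
  monsoon <- person_time_from_influx(pw, c(cfg$monsoon_start,
                                           cfg$monsoon_end))
  expect_lt(abs(full - cfg$pt_total) / cfg$pt_total, 0.01)
  expect_lt(abs(monsoon - cfg$pt_monsoon) / cfg$pt_monsoon, 0.01)
  expect_error(simulate_influx(-1), "positive")
  expect_error(simulate_influx(span = c("1971-05-01", "1971-04-01")),
               "invalid span")
})

test_that("the noiseless limit recovers the truth up to count rounding", {
  exp <- recovery_experiment(simulation_spec(noiseless = TRUE, seed = 5), 5)
  # deaths are rounded expectations, so errors are sub-death-level
  expect_lt(abs(exp$summary$bias_b), 1)
  expect_lt(abs(exp$summary$bias_m), 1)
  expect_lt(exp$summary$rmse_b, 1)
})

test_that("adjusting underreported official counts moves estimates toward truth", {
  cfg <- study_config()
  truth_total <- cfg$pt_total * 174 + cfg$pt_monsoon * 370
  err_unadj <- err_adj <- numeric(20)
  for (i in 1:20) {
    spec <- simulation_spec(underreport_factor = 2.489, seed = 100 + i)
    camps <- simulate_camps(spec, cfg)
    unadj <- excess_with_ci(
      fit_rates(build_design(camps, cfg), cfg),
      loo_variance(build_design(camps, cfg), cfg), cfg
    )
    adj <- adjusted_scenario(camps, cfg)$tolls
    err_unadj[i] <- abs(unadj$total_toll - truth_total)
    err_adj[i] <- abs(adj$total_toll - truth_total)
  }
  expect_lt(mean(err_adj), mean(err_unadj))
})

test_that("run_simulation writes a deterministic CSV + JSON summary", {
  out1 <- withr::local_tempfile(fileext = ".json")
  out2 <- withr::local_tempfile(fileext = ".json")
  spec <- simulation_spec(seed = 21)
  run_simulation(spec, 10, out = out1)
  run_simulation(spec, 10, out = out2)
  expect_identical(readLines(out1), readLines(out2))
  csv <- utils::read.csv(sub("\\.json$", ".csv", out1))
  expect_equal(nrow(csv), 10)
  expect_true(all(c("b", "m", "excess", "covered") %in% names(csv)))
  expect_error(run_simulation(spec, 0), ">= 1")
})
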