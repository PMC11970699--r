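test_that("inclusive day counts reproduce every bundled duration", {
  camps <- refugee_camps_1971()
  expect_equal(
    duration_days(camps$start_date, camps$end_date),
    c(153L, 8L, 12L, 17L, 62L, 30L, 5L, 217L, 25L, 199L, 16L, 61L, 230L,
      230L, 9L, 13L, 21L)
  )
  expect_equal(duration_days("1971-06-01", "1971-06-01"), 1L)
  expect_equal(duration_days("1971-06-01", "1971-12-16"), 199L)
  expect_error(duration_days("1971-07-02", "1971-07-01"), "precedes")
})

test_that("monsoon fractions follow the cause label and the convention", {
  camps <- refugee_camps_1971()
  incl <- monsoon_fraction(camps, study_config())
  pap <- monsoon_fraction(camps, study_config(overlap_convention = "paper"))

  expect_true(all(incl >= 0 & incl <= 1))
  expect_true(all(pap >= 0 & pap <= 1))
  # general rows load only on the baseline rate
  expect_equal(incl[camps$cause_class == "general"], rep(0, 3))
  # the cyclone record lies outside June-September yet is fully
  # monsoon-excess: the label governs, not the calendar
  jambu <- which(camps$camp_name == "Jambu Island")
  expect_equal(incl[jambu], 1)
  expect_equal(pap[jambu], 1)
  # Banjetia and Lalbagh: the paper convention reproduces 121/199
  banjetia <- which(camps$camp_name == "Banjetia and Lalbagh")
  expect_equal(pap[banjetia], 121 / 199)
  expect_equal(round(pap[banjetia], 3), 0.608)
  expect_equal(incl[banjetia], 122 / 199)
  # an all-cause interval entirely inside the window is fully exposed
  hosp <- which(camps$camp_name == "Barasat hospital")
  expect_equal(incl[hosp], 1)
})

test_that("design rows encode person-time and exposure by cause class", {
  camps <- refugee_camps_1971()
  design <- build_design(camps)

  sl <- design[design$camp_name == "Salt Lake" & design$x_b > 0, ]
  expect_equal(sl$person_time, 26.01)
  expect_equal(sl$x_b, 26.01)
  expect_equal(sl$x_m, 0)

  kalyani <- design[design$camp_name == "Kalyani", ]
  expect_equal(kalyani$x_b, 0)
  expect_equal(kalyani$x_m, 50000 * 30 / 1e6) # 1.5

  jail <- design[design$camp_name == "Barasat jail compound", ]
  expect_equal(jail$x_b, 0.651)
  expect_equal(jail$x_m, 0.651 * 122 / 217)

  expect_true(all(design$x_b + design$x_m > 0))
  expect_equal(design$person_time,
               camps$population *
                 as.numeric(duration_days(camps$start_date, camps$end_date)) /
                 1e6)
})

test_that("influx person-time integrates the cumulative curve", {
  # constant 1e6 refugees over 100 days: rectangle
  flat <- influx_series(as.Date("1971-04-01") + c(0, 100), c(1e6, 1e6))
  expect_equal(person_time_from_influx(flat), 100)
  # linear ramp 0 -> 1e6 over 100 days: triangle
  ramp <- influx_series(as.Date("1971-04-01") + c(0, 100), c(0, 1e6))
  expect_equal(person_time_from_influx(ramp), 50)
  # additivity over disjoint windows
  s <- simulate_influx(shape = "logistic")
  d0 <- s$date[1]
  d2 <- s$date[length(s$date)]
  d1 <- as.Date("1971-07-15")
  expect_equal(
    person_time_from_influx(s, c(d0, d1)) +
      person_time_from_influx(s, c(d1, d2)),
    person_time_from_influx(s)
  )
  expect_error(person_time_from_influx(influx_series("1971-04-01", 10)),
               "at least 2")
  expect_error(person_time_from_influx(flat, c("1971-03-01", "1971-05-01")),
               "outside")
})

test_that("trapezoid integration agrees with a daily-step oracle", {
  for (shape in c("linear", "logistic", "piecewise")) {
    s <- simulate_influx(shape = shape, seed = 42)
    got <- person_time_from_influx(s)
    oracle <- daily_step_person_time(s)
    expect_lt(abs(got - oracle) / oracle, 0.001)
  }
})

test_that("influx series validation enforces monotonicity", {
  expect_error(influx_series(c("1971-04-01", "1971-04-01"), c(1, 2)),
               "strictly increasing")
  expect_error(influx_series(c("1971-04-01", "1971-05-01"), c(2, 1)),
               "non-decreasing")
})
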