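test_that("the bundled camp table has the documented shape and flags", {
  camps <- refugee_camps_1971()
  expect_s3_class(camps, "camp_records")
  expect_equal(nrow(camps), 17)
  expect_equal(sum(camps$deaths), 29953)
  expect_equal(sum(camps$official_source), 5)
  flagged <- camps[camps$official_source, ]
  expect_setequal(
    flagged$camp_name,
    c("Salt Lake", "Kalyani", "Nadia district", "Banjetia and Lalbagh",
      "Chapor")
  )
  # the flagged Salt Lake row is the cholera (monsoon-excess) one
  expect_equal(flagged$cause_class[flagged$camp_name == "Salt Lake"],
               "monsoon_excess")
  expect_equal(table(camps$cause_class)[["general"]], 3)
  expect_equal(table(camps$cause_class)[["monsoon_excess"]], 9)
  expect_equal(table(camps$cause_class)[["all"]], 5)
})

test_that("reading a camp CSV returns validated records in file order", {
  path <- withr::local_tempfile(fileext = ".csv")
  salt_lake_csv(path)
  rec <- read_camp_records(path)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$population, 170000)
  expect_equal(rec$deaths, 3671)
  expect_equal(rec$start_date, as.Date("1971-07-01"))
  expect_equal(rec$cause_class, "general")
})

test_that("validation rejects invalid records with row-addressable errors", {
  base <- as.data.frame(refugee_camps_1971())

  bad <- base
  bad$end_date[3] <- as.Date("1971-05-01") # before its start
  expect_error(as_camp_records(bad), "row 3.*end_date.*before start_date")

  bad <- base
  bad$deaths[2] <- bad$population[2] + 1
  expect_error(as_camp_records(bad), "row 2.*deaths.*exceeds population")

  bad <- base
  bad$cause_class[5] <- "cyclone"
  expect_error(as_camp_records(bad), "row 5.*cause_class.*unknown")

  bad <- base
  bad$start_date[1] <- as.Date("1971-01-01") # before the study period
  expect_error(as_camp_records(bad), "row 1.*outside the study period")

  expect_error(as_camp_records(base[, -3]), "missing column")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "camp_name,state,population,deaths,start_date,end_date,cause_class,official_source,source_note",
    "X,WB,1000,10,01/07/1971,1971-07-30,general,FALSE,note"
  ), path)
  expect_error(read_camp_records(path), "row 1.*start_date.*ISO 8601")

  expect_error(read_camp_records(withr::local_tempfile()), "not found")
})

test_that("camp records survive a write/read round trip losslessly", {
  camps <- refugee_camps_1971()
  path <- withr::local_tempfile(fileext = ".csv")
  write_camp_records(camps, path)
  again <- read_camp_records(path)
  expect_equal(as.data.frame(again), as.data.frame(camps))
})

test_that("study_config applies and validates defaults and overrides", {
  cfg <- study_config()
  expect_equal(cfg$cdr_peacetime, 17)
  expect_equal(cfg$pt_total, 1853.65)
  expect_equal(cfg$pt_monsoon, 884.06)
  expect_equal(cfg$age_inflation, 1.545)
  expect_equal(cfg$undercount_factor, 2.489)
  expect_equal(cfg$huber_c, 1.345)
  expect_equal(cfg$overlap_convention, "inclusive")
  expect_equal(study_config(undercount_factor = 2)$undercount_factor, 2)
  expect_error(study_config(pt_total = -1), "positive")
  expect_error(study_config(monsoon_start = "1971-10-01"), "precede")
  expect_error(study_config(nonsense = 1), "unknown option")
  expect_error(study_config(overlap_convention = "exclusive"), "inclusive")
})

test_that("a key-value config file overrides only the keys it names", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# study overrides",
    "cdr_peacetime = 20",
    "overlap_convention = paper",
    "monsoon_end = 1971-09-15"
  ), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$cdr_peacetime, 20)
  expect_equal(cfg$overlap_convention, "paper")
  expect_equal(cfg$monsoon_end, as.Date("1971-09-15"))
  expect_equal(cfg$pt_total, 1853.65) # untouched default

  empty <- withr::local_tempfile(fileext = ".cfg")
  writeLines("", empty)
  expect_equal(read_study_config(empty), study_config())
})

test_that("JSON reports carry the full result and round-trip", {
  out <- withr::local_tempfile(fileext = ".json")
  res <- run_pipeline(out = out)
  rep <- read_report(out)
  expect_setequal(
    intersect(c("config", "design", "rates", "tolls", "uncertainty",
                "adjusted", "manifest"), names(rep)),
    c("config", "design", "rates", "tolls", "uncertainty", "adjusted",
      "manifest")
  )
  expect_false(rep$adjusted)
  expect_equal(rep$tolls$total, res$tolls$total)
  expect_equal(rep$tolls$excess_ci, res$tolls$excess_ci)
  expect_equal(rep$uncertainty$loo_variance, res$uncertainty$loo_variance)
  expect_equal(nrow(rep$design), 17)

  out2 <- withr::local_tempfile(fileext = ".json")
  run_pipeline(adjusted = TRUE, out = out2)
  expect_true(read_report(out2)$adjusted)

  expect_error(write_report(list(config = 1), out), "incomplete")
})
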