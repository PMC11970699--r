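#' Validate a data frame of camp records
#'
#' A camp record describes one reported death count: the camp population,
#' the number of deaths, the calendar interval the count covers, and a
#' cause class saying which death rate the count reflects (`"general"`
#' for baseline-only deaths, `"monsoon_excess"` for counts attributed
#' entirely to monsoon-specific hazards such as cholera or cyclone, and
#' `"all"` for all-cause counts spanning both). `official_source` marks
#' rows whose counts come from official tallies and are therefore
#' eligible for the undercount adjustment of [adjusted_scenario()].
#'
#' Invariants enforced (with row-addressable errors):
#' * `end_date >= start_date`, both within 1971-03-25 .. 1971-12-16;
#' * `deaths <= population`, `population > 0`, `deaths >= 0`;
#' * `cause_class` one of `"general"`, `"monsoon_excess"`, `"all"`.
#'
#' The cause label governs which rate applies independently of the
#' calendar: a `monsoon_excess` record may lie outside the monsoon
#' window (e.g. a cyclone), and still loads only on the monsoon rate.
#'
#' @param x A data frame with columns `camp_name`, `state`, `population`,
#'   `deaths`, `start_date`, `end_date`, `cause_class`,
#'   `official_source`, `source_note`.
#' @return `x`, with dates as `Date` and class `camp_records` prepended.
#' @export
as_camp_records <- function(x) {
  required <- c(
    "camp_name", "state", "population", "deaths", "start_date",
    "end_date", "cause_class", "official_source", "source_note"
  )
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("camp records: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[required]

  parse_date <- function(col) {
    v <- x[[col]]
    if (!inherits(v, "Date")) v <- as.Date(as.character(v), format = "%Y-%m-%d")
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("camp records row %d: field '%s' is not an ISO 8601 date",
                   bad[1], col), call. = FALSE)
    }
    v
  }
  x$start_date <- parse_date("start_date")
  x$end_date <- parse_date("end_date")
  x$population <- as.numeric(x$population)
  x$deaths <- as.numeric(x$deaths)
  x$official_source <- as.logical(x$official_source)

  fail <- function(i, field, msg) {
    stop(sprintf("camp records row %d (%s): field '%s' %s",
                 i, x$camp_name[i], field, msg), call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    if (is.na(x$population[i]) || x$population[i] <= 0 ||
        x$population[i] != round(x$population[i])) {
      fail(i, "population", "must be a positive integer")
    }
    if (is.na(x$deaths[i]) || x$deaths[i] < 0 ||
        x$deaths[i] != round(x$deaths[i])) {
      fail(i, "deaths", "must be a non-negative integer")
    }
    if (x$deaths[i] > x$population[i]) {
      fail(i, "deaths", "exceeds population")
    }
    if (x$end_date[i] < x$start_date[i]) {
      fail(i, "end_date", "is before start_date")
    }
    if (x$start_date[i] < study_start || x$end_date[i] > study_end) {
      fail(i, "start_date/end_date",
           sprintf("outside the study period %s .. %s",
                   format(study_start), format(study_end)))
    }
    if (!(x$cause_class[i] %in% cause_classes)) {
      fail(i, "cause_class",
           sprintf("unknown ('%s'); must be one of %s", x$cause_class[i],
                   paste(cause_classes, collapse = ", ")))
    }
    if (is.na(x$official_source[i])) {
      fail(i, "official_source", "must be TRUE or FALSE")
    }
  }
  class(x) <- c("camp_records", "data.frame")
  x
}

#' Read camp records from a CSV file
#'
#' The file must have a header row with the documented schema
#' (`camp_name, state, population, deaths, start_date, end_date,
#' cause_class, official_source, source_note`) and ISO 8601 dates. All
#' record invariants are enforced; violations raise an error naming the
#' offending row and field.
#'
#' @param path Path to a CSV file.
#' @return A validated `camp_records` data frame, in file order.
#' @seealso [refugee_camps_1971()] for the bundled study dataset.
#' @export
read_camp_records <- function(path) {
  if (!file.exists(path)) {
    stop("camp records file not found: ", path, call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  as_camp_records(x)
}

#' Write camp records to a CSV file
#'
#' Inverse of [read_camp_records()]: loading the written file yields
#' identical records.
#'
#' @param x A `camp_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_camp_records <- function(x, path) {
  x <- as_camp_records(x)
  out <- as.data.frame(x)
  out$start_date <- format(out$start_date, "%Y-%m-%d")
  out$end_date <- format(out$end_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The 17 reported refugee-camp death tolls used in the study
#'
#' The bundled dataset of reported death counts in Bangladeshi refugee
#' camps across India in 1971: 17 records from camp surveys, official
#' statements and contemporary news reports, spanning West Bengal,
#' Meghalaya, Assam, Orissa and Madhya Pradesh. Five records whose
#' counts come from official tallies (the Salt Lake cholera count,
#' Kalyani, Nadia district, Banjetia and Lalbagh, and Chapor) carry
#' `official_source = TRUE` and are the rows inflated by the
#' undercount-adjustment scenario.
#'
#' @return A validated `camp_records` data frame with 17 rows.
#' @export
#' @examples
#' camps <- refugee_camps_1971()
#' nrow(camps)
#' sum(camps$deaths)
refugee_camps_1971 <- function() {
  path <- system.file("extdata", "camps_1971.csv", package = "camptoll",
                      mustWork = TRUE)
  read_camp_records(path)
}

#' Study configuration constants
#'
#' All scalar constants of the analysis, with the study defaults:
#'
#' * `cdr_peacetime`: peacetime crude death rate, deaths per 1000
#'   persons per year (17, the 1971 Bangladesh nationwide estimate);
#' * `monsoon_start`, `monsoon_end`: the 1971 monsoon window
#'   (June 1 - September 30);
#' * `pt_total`: total person-time spent by all refugees in India,
#'   million person-days (1853.65, from the official influx records);
#' * `pt_monsoon`: person-time within the monsoon window, million
#'   person-days (884.06);
#' * `age_inflation`: SD multiplier accounting for age-stratified
#'   mortality heterogeneity (1.545);
#' * `undercount_factor`: multiplier applied to official death counts in
#'   the adjustment scenario (2.489);
#' * `ci_halfwidth_sds`: confidence-interval half-width in adjusted SDs
#'   (2, an approximate 95% interval);
#' * `huber_c`: Huber tuning constant of the robust regression (1.345);
#' * `overlap_convention`: `"inclusive"` (default) counts monsoon
#'   overlap days inclusively, like interval durations; `"paper"` counts
#'   the overlap as a date difference, reproducing the printed 121/199
#'   monsoon fraction for the Banjetia and Lalbagh record.
#'
#' @param ... Named overrides of the defaults above.
#' @return A `study_config` list.
#' @export
#' @examples
#' study_config()$pt_total
#' study_config(undercount_factor = 2)$undercount_factor
study_config <- function(...) {
  cfg <- list(
    cdr_peacetime = 17,
    monsoon_start = as.Date("1971-06-01"),
    monsoon_end = as.Date("1971-09-30"),
    pt_total = 1853.65,
    pt_monsoon = 884.06,
    age_inflation = 1.545,
    undercount_factor = 2.489,
    ci_halfwidth_sds = 2,
    huber_c = 1.345,
    overlap_convention = "inclusive"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("study_config: unknown option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg$monsoon_start <- as.Date(cfg$monsoon_start)
  cfg$monsoon_end <- as.Date(cfg$monsoon_end)
  for (f in c("cdr_peacetime", "pt_total", "pt_monsoon", "age_inflation",
              "undercount_factor", "ci_halfwidth_sds", "huber_c")) {
    cfg[[f]] <- as.numeric(cfg[[f]])
    if (!is.finite(cfg[[f]]) && f != "huber_c") {
      stop("study_config: '", f, "' must be finite", call. = FALSE)
    }
    if (cfg[[f]] <= 0) stop("study_config: '", f, "' must be positive",
                            call. = FALSE)
  }
  if (cfg$monsoon_start >= cfg$monsoon_end) {
    stop("study_config: monsoon_start must precede monsoon_end", call. = FALSE)
  }
  if (!(cfg$overlap_convention %in% c("inclusive", "paper"))) {
    stop("study_config: overlap_convention must be 'inclusive' or 'paper'",
         call. = FALSE)
  }
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from a key-value text file
#'
#' The file holds one `key = value` pair per line; `#` starts a comment.
#' Every key is optional and defaults to the values documented in
#' [study_config()], so an empty file reproduces the study defaults.
#'
#' @param path Path to the config file.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config: cannot parse line (expected 'key = value'): ", ln,
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  numeric_keys <- c("cdr_peacetime", "pt_total", "pt_monsoon",
                    "age_inflation", "undercount_factor",
                    "ci_halfwidth_sds", "huber_c")
  for (k in intersect(names(kv), numeric_keys)) kv[[k]] <- as.numeric(kv[[k]])
  do.call(study_config, kv)
}

# Serialize a config for reports (dates to ISO strings).
config_as_list <- function(config) {
  out <- unclass(config)
  out$monsoon_start <- format(out$monsoon_start, "%Y-%m-%d")
  out$monsoon_end <- format(out$monsoon_end, "%Y-%m-%d")
  out
}

#' Write a pipeline result to a JSON report
#'
#' The report carries the top-level keys `config`, `design`, `rates`,
#' `tolls`, `uncertainty`, `adjusted` (plus a `manifest` when produced by
#' [run_pipeline()]). Numbers are written at full precision so that a
#' round-trip through [read_report()] is lossless to double precision.
#'
#' @param result A `pipeline_result`, as returned by [run_pipeline()].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  needed <- c("config", "design", "rates", "tolls", "uncertainty", "adjusted")
  missing_keys <- setdiff(needed, names(result))
  if (length(missing_keys) > 0) {
    stop("write_report: result is incomplete; missing: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the JSON report.
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
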