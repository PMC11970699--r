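#' Run the full death-toll estimation pipeline
#'
#' Executes the complete analysis — design construction, robust two-rate
#' fit, toll projection, leave-one-out variance, and the excess-toll
#' confidence interval — on a camp table, optionally under the
#' undercount-adjustment scenario, and (optionally) writes a JSON report
#' with a run manifest.
#'
#' @param camps `"bundled"` (default) for the packaged 17-record study
#'   table, a path to a camp CSV, or a `camp_records` data frame.
#' @param config A [study_config()] or a path to a key-value config file.
#' @param adjusted If `TRUE`, inflate official death counts by
#'   `config$undercount_factor` before the analysis.
#' @param out Optional path; when given, the report is written there as
#'   JSON via [write_report()].
#' @return A `pipeline_result` list with keys `config`, `design`,
#'   `rates`, `tolls`, `uncertainty`, `adjusted`, `manifest`; its
#'   `$tolls` element is the `toll_result`.
#' @export
#' @examples
#' res <- run_pipeline()
#' res$tolls$excess_toll
run_pipeline <- function(camps = "bundled", config = study_config(),
                         adjusted = FALSE, out = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))

  camps_path <- NULL
  if (is.character(camps) && length(camps) == 1 && camps == "bundled") {
    camps_path <- system.file("extdata", "camps_1971.csv",
                              package = "camptoll", mustWork = TRUE)
    records <- read_camp_records(camps_path)
  } else if (is.character(camps)) {
    camps_path <- camps
    records <- read_camp_records(camps)
  } else {
    records <- as_camp_records(camps)
  }

  if (adjusted) {
    scenario <- adjusted_scenario(records, config)
    design <- scenario$design
    rates <- scenario$rates
    loo <- scenario$loo
    tolls <- scenario$tolls
  } else {
    design <- build_design(records, config)
    rates <- fit_rates(design, config)
    loo <- loo_variance(design, config)
    tolls <- excess_with_ci(rates, loo, config)
  }

  result <- list(
    config = config_as_list(config),
    design = as.data.frame(design),
    rates = list(
      b = rates$b,
      m = rates$m,
      b_per_1000_year = convert_rate(rates$b, "per_million_person_day",
                                     "per_1000_person_year"),
      m_per_1000_year = convert_rate(rates$m, "per_million_person_day",
                                     "per_1000_person_year"),
      converged = rates$converged,
      iterations = rates$iterations,
      scale = rates$scale,
      weights = rates$weights
    ),
    tolls = list(
      natural = tolls$natural_toll,
      natural_ci = unname(tolls$natural_ci),
      baseline = tolls$baseline_toll,
      monsoon = tolls$monsoon_toll,
      total = tolls$total_toll,
      excess = tolls$excess_toll,
      excess_ci = unname(tolls$excess_ci)
    ),
    uncertainty = list(
      loo_totals = loo$loo_totals,
      loo_variance = loo$loo_variance,
      denominator_convention = loo$denominator_convention,
      total_variance = tolls$total_variance,
      excess_variance = tolls$excess_variance,
      excess_se_unadjusted = tolls$excess_se_unadjusted,
      excess_sd_adjusted = tolls$excess_sd_adjusted,
      se_b_jackknife = loo$se_b,
      se_m_jackknife = loo$se_m
    ),
    adjusted = adjusted,
    manifest = run_manifest(config, camps_path)
  )
  if (adjusted) result$undercount_factor <- config$undercount_factor
  class(result) <- "pipeline_result"
  attr(result, "toll_result") <- tolls
  if (!is.null(out)) {
    report <- unclass(result)
    attr(report, "toll_result") <- NULL
    write_report(report, out)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("camptoll pipeline (%s)\n",
              if (isTRUE(x$adjusted)) "undercount-adjusted scenario"
              else "unadjusted"))
  cat(sprintf("  b = %.2f, m = %.2f deaths per million person-days\n",
              x$rates$b, x$rates$m))
  print(attr(x, "toll_result"))
  invisible(x)
}

# Manifest embedded in every report: command echo, config hash, input
# digests, package version, timestamp.
run_manifest <- function(config, camps_path = NULL) {
  cfg_string <- paste(
    vapply(config_as_list(config), function(v) paste(format(v), collapse = ","),
           character(1)),
    collapse = ";"
  )
  tf <- tempfile()
  writeLines(cfg_string, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  digests <- if (!is.null(camps_path) && file.exists(camps_path)) {
    as.list(tools::md5sum(camps_path))
  } else {
    list()
  }
  list(
    command = paste(commandArgs(), collapse = " "),
    config_hash = cfg_hash,
    input_digests = digests,
    package_version = as.character(utils::packageVersion("camptoll")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Run a simulation harness and write its summary
#'
#' Thin wrapper around [recovery_experiment()] that writes the
#' per-replicate results as CSV and the summary (with the simulation
#' spec) as JSON.
#'
#' @param spec A [simulation_spec()].
#' @param replicates Number of replicates (>= 1).
#' @param out Optional output path for the JSON summary; the
#'   per-replicate CSV is written next to it with extension `.csv`.
#' @param config A [study_config()].
#' @return The `recovery_experiment`, invisibly.
#' @export
run_simulation <- function(spec, replicates, out = NULL,
                           config = study_config()) {
  exp <- recovery_experiment(spec, replicates, config)
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    csv_path <- if (grepl("\\.json$", out)) sub("\\.json$", ".csv", out) else
      paste0(out, ".csv")
    utils::write.csv(exp$results, csv_path, row.names = FALSE)
    spec_list <- unclass(exp$spec)
    spec_list$date_span <- format(spec_list$date_span, "%Y-%m-%d")
    spec_list$cause_mix <- as.list(spec_list$cause_mix)
    jsonlite::write_json(
      list(spec = spec_list, summary = exp$summary),
      out, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(exp)
}
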