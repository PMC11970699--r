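rate_units <- c("per_million_person_day", "per_1000_person_year")

#' Convert a death rate between units
#'
#' The two supported units are deaths per million person-days and deaths
#' per 1000 person-years; the conversion factor is 365/1000 (a rate per
#' million person-days times 0.365 gives the rate per 1000 person-years,
#' so the peacetime CDR of 17 per 1000/yr is 46.575 per million/day).
#'
#' @param value Numeric rate value(s).
#' @param from,to Units, each one of `"per_million_person_day"`,
#'   `"per_1000_person_year"`.
#' @return The rate expressed in `to` units.
#' @export
#' @examples
#' convert_rate(17, "per_1000_person_year", "per_million_person_day")
convert_rate <- function(value, from, to) {
  from <- match.arg(from, rate_units)
  to <- match.arg(to, rate_units)
  if (from == to) return(value)
  if (from == "per_million_person_day") value * 365 / 1000 else
    value * 1000 / 365
}

#' Expected natural death toll under the peacetime death rate
#'
#' The number of deaths expected among the refugees had peacetime
#' mortality prevailed: the peacetime CDR converted to per million
#' person-days (kept at full precision, `cdr * 1000 / 365`) times the
#' total person-time. Under the binomial model with small per-day death
#' probability the variance of a death count equals its mean, so the
#' binomial SD is the square root of the toll; the adjusted SD
#' multiplies it by the age-stratification inflation factor, and the
#' confidence interval extends `ci_halfwidth_sds` adjusted SDs either
#' side.
#'
#' @param config A [study_config()].
#' @return A list: `toll`, `sd_binomial`, `sd_adjusted`,
#'   `ci = c(lower, upper)` (all in deaths).
#' @export
#' @examples
#' natural_toll()$toll # about 86,334 deaths
natural_toll <- function(config = study_config()) {
  rate <- convert_rate(config$cdr_peacetime, "per_1000_person_year",
                       "per_million_person_day")
  toll <- config$pt_total * rate
  sd_binomial <- sqrt(toll)
  sd_adjusted <- sd_binomial * config$age_inflation
  half <- config$ci_halfwidth_sds * sd_adjusted
  list(
    toll = toll,
    sd_binomial = sd_binomial,
    sd_adjusted = sd_adjusted,
    ci = c(lower = toll - half, upper = toll + half)
  )
}

#' Baseline, monsoon and total death tolls from fitted rates
#'
#' Projects the fitted rates onto the population-level person-time
#' aggregates: the baseline toll is `pt_total * b`, the monsoon toll is
#' `pt_monsoon * m`, and the total is their sum.
#'
#' @param rates A `rate_fit` (or any list with elements `b` and `m`, in
#'   deaths per million person-days).
#' @param config A [study_config()].
#' @return A list: `baseline`, `monsoon`, `total` (deaths).
#' @export
toll_components <- function(rates, config = study_config()) {
  baseline <- config$pt_total * rates$b
  monsoon <- config$pt_monsoon * rates$m
  list(baseline = baseline, monsoon = monsoon, total = baseline + monsoon)
}

#' Death-rate ratio between crisis and peacetime rates
#'
#' @param crisis_rate,peacetime_rate Numeric rates.
#' @param crisis_unit,peacetime_unit Units of the two rates; they are
#'   harmonised internally before dividing.
#' @return The dimensionless ratio crisis / peacetime.
#' @export
#' @examples
#' rate_ratio(63.52, 17) # baseline vs peacetime CDR
rate_ratio <- function(crisis_rate, peacetime_rate,
                       crisis_unit = "per_1000_person_year",
                       peacetime_unit = "per_1000_person_year") {
  if (any(peacetime_rate == 0)) {
    stop("rate_ratio: peacetime rate is zero", call. = FALSE)
  }
  crisis_rate / convert_rate(peacetime_rate, peacetime_unit, crisis_unit)
}
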