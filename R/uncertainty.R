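#' Leave-one-out variance of the projected total death toll
#'
#' Quantifies the variability of the total toll due to variation across
#' source records: for each design row in turn, the two-rate model is
#' refitted on the remaining rows and the total toll recomputed via
#' [toll_components()]; the variance of the resulting totals (default
#' denominator `n - 1`) is the leave-one-out variance. This is a
#' jackknife taken literally on the totals, without the `(n-1)/n`
#' rescaling.
#'
#' @param design A `camp_design` with at least 3 rows; every
#'   leave-one-out design must remain identifiable.
#' @param config A [study_config()].
#' @param denominator `"n_minus_1"` (default) or `"n"`.
#' @return A `loo_result`: `loo_totals` (one per omitted row),
#'   `loo_b`, `loo_m`, `loo_variance`, `denominator_convention`, and the
#'   jackknife standard errors `se_b`, `se_m` of the two rates.
#' @export
loo_variance <- function(design, config = study_config(),
                         denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  n <- nrow(design)
  if (n < 3) stop("loo_variance: need at least 3 design rows", call. = FALSE)
  totals <- numeric(n)
  bs <- numeric(n)
  ms <- numeric(n)
  for (i in seq_len(n)) {
    sub <- design[-i, , drop = FALSE]
    # Warnings (e.g. a negative coefficient when the anchoring row is
    # dropped) are expected in leave-one-out refits and not surfaced.
    fit <- tryCatch(
      suppressWarnings(fit_rates(sub, config)),
      error = function(e) {
        stop(sprintf("loo_variance: degenerate fit when omitting row %d (%s): %s",
                     i, design$camp_name[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
    bs[i] <- fit$b
    ms[i] <- fit$m
    totals[i] <- toll_components(fit, config)$total
  }
  div <- if (denominator == "n_minus_1") n - 1 else n
  centred <- totals - mean(totals)
  v <- sum(centred^2) / div
  # Standard jackknife SEs for the individual coefficients.
  jk_se <- function(th) sqrt((n - 1) / n * sum((th - mean(th))^2))
  structure(
    list(
      loo_totals = totals,
      loo_b = bs,
      loo_m = ms,
      loo_variance = v,
      denominator_convention = denominator,
      se_b = jk_se(bs),
      se_m = jk_se(ms)
    ),
    class = "loo_result"
  )
}

#' Excess death toll with composed variance and confidence interval
#'
#' Combines every variance component of the analysis into the final
#' excess-toll estimate:
#'
#' * `total_variance = total_toll + loo_variance` (binomial count
#'   variance, approximately equal to the mean, plus source-data
#'   variability);
#' * `excess_variance = natural_toll + total_variance` (the natural and
#'   total tolls are estimated independently, and the natural-toll term
#'   is the unadjusted binomial variance);
#' * `excess_sd_adjusted = sqrt(excess_variance) * age_inflation`
#'   (the age-stratification inflation multiplies the combined SE once,
#'   at the end);
#' * the interval is `excess ± ci_halfwidth_sds * excess_sd_adjusted`.
#'
#' @param rates A `rate_fit` from [fit_rates()].
#' @param loo A `loo_result` from [loo_variance()].
#' @param config A [study_config()].
#' @return A `toll_result` with the natural, baseline, monsoon, total
#'   and excess tolls, all variance components, and both confidence
#'   intervals.
#' @export
excess_with_ci <- function(rates, loo, config = study_config()) {
  if (loo$loo_variance < 0) {
    stop("excess_with_ci: negative leave-one-out variance", call. = FALSE)
  }
  nat <- natural_toll(config)
  comp <- toll_components(rates, config)
  total_variance_binomial <- comp$total
  total_variance <- total_variance_binomial + loo$loo_variance
  excess <- comp$total - nat$toll
  excess_variance <- nat$toll + total_variance
  excess_se <- sqrt(excess_variance)
  excess_sd_adjusted <- excess_se * config$age_inflation
  half <- config$ci_halfwidth_sds * excess_sd_adjusted
  structure(
    list(
      natural_toll = nat$toll,
      natural_sd_binomial = nat$sd_binomial,
      natural_sd_adjusted = nat$sd_adjusted,
      natural_ci = nat$ci,
      baseline_toll = comp$baseline,
      monsoon_toll = comp$monsoon,
      total_toll = comp$total,
      total_variance_binomial = total_variance_binomial,
      loo_variance = loo$loo_variance,
      total_variance = total_variance,
      excess_toll = excess,
      excess_variance = excess_variance,
      excess_se_unadjusted = excess_se,
      excess_sd_adjusted = excess_sd_adjusted,
      excess_ci = c(lower = excess - half, upper = excess + half)
    ),
    class = "toll_result"
  )
}

#' @export
print.toll_result <- function(x, ...) {
  f <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Death-toll estimates (deaths)\n")
  cat(sprintf("  natural  : %s  (CI %s - %s)\n", f(x$natural_toll),
              f(x$natural_ci[["lower"]]), f(x$natural_ci[["upper"]])))
  cat(sprintf("  baseline : %s\n", f(x$baseline_toll)))
  cat(sprintf("  monsoon  : %s\n", f(x$monsoon_toll)))
  cat(sprintf("  total    : %s\n", f(x$total_toll)))
  cat(sprintf("  excess   : %s  (CI %s - %s)\n", f(x$excess_toll),
              f(x$excess_ci[["lower"]]), f(x$excess_ci[["upper"]])))
  cat(sprintf("  adjusted excess SD: %s\n", f(x$excess_sd_adjusted)))
  invisible(x)
}
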