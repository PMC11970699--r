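---
title: "A two-rate binomial person-time model for 1971 refugee-camp mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-rate binomial person-time model for 1971 refugee-camp mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camptoll)
```

## The estimation problem

During the 1971 Bangladesh liberation war roughly 9.9 million refugees
crossed into India and lived, until the surrender on 16 December 1971,
in about a thousand camps under conditions that drove mortality far
above peacetime levels — especially during the June–September monsoon,
when cholera and other epidemics swept the camps. No systematic
mortality registration existed. What survives is a small set of
reported death counts: 17 records from camp surveys, official
statements, and contemporary news reports, each covering one camp, one
calendar interval, and one class of causes. `camptoll` turns those
records into an estimate of the total and *excess* death toll (deaths
above what peacetime mortality would have produced over the same
person-time), with an uncertainty statement.

## Model

Deaths in a camp are modelled as a binomial count over person-time. If
a camp holds $n$ person-days of exposure and the per-person-day death
probability is $p$, the reported count is $r \sim \mathrm{Bin}(n, p)$,
with $E(r) = np$ and, because $p$ is tiny (a few hundred per million
person-days at worst), $V(r) \approx np$: the variance of a count
equals its mean.

Two hazards are distinguished:

* $b$ — the baseline death rate from general causes, applicable
  year-round;
* $m$ — the *additional* death rate during the monsoon (epidemics,
  floods), so the total monsoon-period rate is $b + m$.

Both are measured in deaths per million person-days; multiplying by
$0.365$ converts to the demographer's deaths per 1000 person-years.

Each record declares, through its cause class, which hazard its count
reflects. A "general deaths only" record with person-time $x$
contributes the equation $b \, x = r$; a cholera- or cyclone-only
record contributes $m \, x = r$; an all-cause record contributes
$b \, x + m \, f x = r$, where $f$ is the fraction of its duration that
overlaps the monsoon window. The label governs, not the calendar: a
cyclone record in late October still loads only on $m$, because its
count excludes baseline deaths by construction.

Person-time per camp is `population * duration / 1e6` million
person-days, taking the reported (final) camp population over the whole
interval. Because camps filled gradually, this overstates exposure and
therefore understates rates — a deliberately conservative choice
inherited from the source records.

## Calendar conventions

Durations are counted inclusively (`end - start + 1`), which reproduces
every printed duration in the bundled table. For the monsoon-overlap
fraction of all-cause records, two conventions are available:

* `overlap_convention = "inclusive"` (default): the overlap is an
  inclusive day count, like durations. For the Banjetia and Lalbagh
  record (1 June – 16 December) this gives $122/199 \approx 0.613$.
* `"paper"`: the overlap is a plain date difference, giving the
  published $121/199 = 0.608$ for that record.

The published analysis prints the 0.608 fraction but counts durations
inclusively, so no single convention matches both; the default stays
with the self-consistent inclusive count. The choice moves every
downstream estimate by well under 1%.

## Estimation

With 17 equations and two unknowns, $(b, m)$ is estimated by linear
regression of the death counts on the two exposure columns, without
intercept. The records differ enormously in scale and quality (Salt
Lake contributes 26 million person-days; Barasat hospital 0.175), so
the fit is robust: Huber M-estimation via iteratively reweighted least
squares,

1. start at the ordinary least-squares solution;
2. residual scale $s = \mathrm{median}(|r_i|)/0.6745$ (re-estimated
   every iteration);
3. weights $w_i = \min(1,\ c\,s/|r_i|)$ with tuning constant
   $c = 1.345$;
4. weighted least squares, iterated to a relative coefficient change
   below $10^{-8}$ (at most 200 iterations).

Numerical choices worth noting: a zero-residual fit short-circuits with
unit weights (the scale is zero and no reweighting is meaningful);
$c = \infty$ reproduces ordinary least squares exactly, which the test
suite checks against a closed-form normal-equations oracle; degenerate
designs (an exposure column that is all zeros, or collinear columns)
are rejected up front. The response is the raw death count, not the
rate — matching the per-camp equations above — and no heteroscedasticity
weighting is applied, mirroring the published procedure. On the bundled
design the implementation agrees with `MASS::rlm` (Huber, MAD scale) to
better than 0.1%.

A caveat the package surfaces honestly: the published baseline/monsoon
coefficient split is sensitive to fitting conventions that the original
description leaves unstated. This implementation (and `MASS::rlm`
under its documented defaults) produces a different split of the two
rates than the published pair, while agreeing with the published
*total* toll within about 1%. The totals are the stable functional of
the data; the individual coefficients are not.

## From rates to tolls

Tolls are linear projections onto population-level person-time
aggregates taken from the official influx records: a total of 1853.65
million person-days, of which 884.06 million fall inside the monsoon
window. Then

* natural toll $= 1853.65 \times (17 \times 1000/365)$, the peacetime
  crude death rate of 17 per 1000 per year applied at full precision;
* baseline toll $= 1853.65 \, \hat b$; monsoon toll
  $= 884.06 \, \hat m$; total $=$ their sum;
* excess toll $=$ total $-$ natural.

All internal rate arithmetic stays in per-million-person-day units at
full precision; rounded display values (46.575, 0.608) are never used
as inputs, because the published arithmetic itself follows the
full-precision values.

## Uncertainty

Three components are composed:

1. **Binomial count variance** of each toll, equal to the toll itself
   (variance $\approx$ mean).
2. **Source-data variability**, via leave-one-out refits: each of the
   17 records is dropped in turn, the model refitted, and the total
   toll recomputed; the variance of the 17 resulting totals (default
   denominator $n-1$; denominator $n$ is also implemented and changes
   the result by 6%) is added to the binomial variance. This is the
   published procedure taken literally. Note that it is *not* the
   standard jackknife variance, which would multiply the spread of the
   leave-one-out values by $(n-1)^2/n \approx 15$; the coverage
   experiment below quantifies the consequence.
3. **Age-stratification inflation**: the combined standard error is
   multiplied once, at the end, by 1.545, a constant derived from
   age-stratified survey data and consumed here as a given. The
   natural-toll variance entering the composition is the unadjusted
   binomial one.

The excess-toll interval is the estimate $\pm 2$ adjusted SDs.

## What the synthetic generator emulates — and what it does not

`simulate_camps()` draws each camp's death count from a single
$\mathrm{Bin}(\text{population} \times \text{days},\ \text{rate}/10^6)$
— exactly the model the inference assumes, rather than a day-by-day
survival process, so that estimator properties can be tested under the
model's own assumptions. Defaults mirror the bundled table: 17 camps,
true rates $(b, m) = (174, 370)$ per million person-days, populations
3,000–250,000, intervals of 5–120 days inside the 10 April – 15
December influx window, and the observed cause-class mix (3 general, 9
monsoon-excess, 5 all-cause in 17). An `underreport_factor` divides
counts before output and flags the rows as official sources, so the
undercount adjustment can be exercised against a known truth; a
`noiseless` mode replaces draws by rounded expectations (exact only up
to integer rounding of each count, since records carry integer deaths).

What the generator deliberately does **not** emulate is the
overdispersion of the real records, whose residual spread exceeds
binomial noise by orders of magnitude (source heterogeneity, reporting
error, cause misclassification). This matters for interpreting the
validation results: under clean binomial data the leave-one-out
variance of component 2 *understates* the estimator's sampling variance
(the missing $(n-1)^2/n$ jackknife factor), and the $\pm 2$ SD interval
covers the true excess toll in only about 70% of replicates — the
coverage check in the acceptance suite asserts the nominal 90% and
fails, by design, to document this property. On the real records the
procedure produces a wide interval anyway, because the observed
heterogeneity inflates the leave-one-out spread far beyond the binomial
floor. Passing recovery tests therefore demonstrate unbiasedness and
correct plumbing, not that the published interval construction is
calibrated under the binomial model.

`simulate_influx()` provides monotone cumulative influx curves (linear,
logistic, or piecewise). The piecewise shape is calibrated in closed
form so its person-time integrals reproduce both aggregate constants
(1853.65 and 884.06 million person-days); satisfying both with a
monotone curve reaching 9.9 million forces a front-loaded shape — a
steep early ramp to about 4.6 million, a plateau before June, a linear
monsoon rise — which is a property of the constraint pair, not a
historical claim.

## Problem sizes and reproducibility

The validation experiments use 200 replicates at the default
simulation spec for coverage and parameter-recovery checks, and 20
paired replicates for the undercount-adjustment comparison; these sizes
put Monte-Carlo noise on a coverage proportion near $\pm 1.5$ and run
in seconds. Every stochastic routine takes an explicit seed and
restores the global RNG state; the full pipeline itself is
deterministic.

## Known limitations

* Records outside camps (a third of the refugee population), wayside
  deaths, and births are absent from the source data; the published
  analysis argues, and this package inherits, that the estimate is an
  undercount.
* The undercount factor 2.489 and the SD inflation 1.545 are consumed
  as constants; their derivations are out of scope.
* The two-rate split $(\hat b, \hat m)$ should be read jointly with its
  instability under fitting conventions (see *Estimation*); the total
  and excess tolls are the robust outputs.
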