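---
title: "Small-area estimation of crisis-attributable mortality: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of crisis-attributable mortality: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortsae)
```

## The estimation problem

In protracted humanitarian crises there is usually no functioning death
registration, yet many retrospective household mortality surveys (SMART-type
cluster surveys) are conducted piecemeal across the affected region. `mortsae`
combines these surveys with reconstructed population denominators and
district-month predictor series to estimate the crude death rate (CDR) and
under-5 death rate (U5DR) for *every* district (LGA) and month — including
strata never surveyed — and to convert rates into death tolls under observed
and counterfactual (no-crisis) conditions. The difference between the two is
the crisis-attributable excess.

The pipeline has six steps, each an independently testable module:

1. **Survey reanalysis** — household records are converted to person-time and
   demographic rates; surveys with incomplete data or implausible estimates
   are excluded; a robustness weight (quality score x sampling coverage, in
   [0, 1]) downweights weak surveys in all model fitting.
2. **Denominators** — multiple graded point-in-time population sources are
   projected by compound monthly growth, combined as a grade-weighted mean,
   and adjusted for cumulative displacement flows (internal moves conserve
   people; an `"external"` sink models refugee outflow).
3. **Predictor preparation** — district-month series are imputed (linear in
   time, nearest-value at the edges), optionally smoothed with trailing
   rolling means, lagged, banded into ordered categories, converted to
   per-capita rates, and averaged over each survey's recall window.
4. **Model selection** — a weighted quasi-Poisson regression of household
   death counts with `log(person-time)` offset; predictors are screened over
   lags and codings, combined into all candidate subsets, and ranked by the
   Dawid–Sebastiani score (DSS) on district-grouped 10-fold cross-validation;
   a district random intercept is retained if it improves CV-DSS.
5. **Excess estimation** — per-stratum log-rate predictions and standard
   errors feed a parametric lognormal bootstrap (1,000 draws per stratum by
   default); draws are multiplied by person-time, summed draw-wise into
   groups, and differenced against counterfactual scenarios.
6. **Sensitivity** — denominator bias (population ratio 0.7–1.3, IDP ratio
   0.5–1.5), under-5 death under-ascertainment (up to 50% missed), and
   death-rate inflation (up to 2x) in strata inaccessible to humanitarian
   actors.

## Person-time accounting

Each current household member contributes the full recall period `R`; every
reported event person — death, birth, arrival, departure — contributes `R/2`
(present from, or until, the midpoint of the window). Child-time is computed
from current under-5 membership plus half-period contributions for under-5
deaths. Under this convention `n_current_members` counts the full-period
membership, and event persons add on top; the test suite checks the
arithmetic against a half-day brute-force enumeration with all events at the
midpoint. A death therefore also credits its own half-period of exposure,
which makes the offset very mildly outcome-dependent; see *Numerical notes*.

Rates follow humanitarian conventions: CDR and U5DR in deaths per 10,000
person-days (child-days), crude birth and net migration rates per 1,000
person-years (multiply a per-10,000-person-day rate by 36.5 to obtain per
1,000 person-years).

## The rate model

For household \(i\) in district \(g\) with death count \(y_i\), person-time
\(t_i\) and recall-averaged predictors \(x_i\):

\[ y_i \sim \text{quasi-Poisson}(\mu_i, \phi), \qquad
   \log \mu_i = x_i^\top \beta + u_g + \log t_i, \qquad
   u_g \sim N(0, \sigma_u^2), \]

weighted by the survey robustness weight. The dispersion \(\phi\) is the
Pearson chi-square over residual degrees of freedom on the training fit; the
coefficient covariance is scaled by \(\max(\phi, 1)\). The floor reflects two
judgements: variance shrinkage below Poisson is not credible for mortality
counts, and at small expected counts the midpoint convention itself biases
the Pearson statistic slightly downward (below). The raw \(\phi\) is always
reported unaltered. The fixed fit uses `stats::glm`; the random-intercept fit
uses Laplace-approximated maximum likelihood via `glmmTMB`, with the same
Pearson-based dispersion scaling applied to the fixed-effect covariance.

### Selection procedure

(i) For each variable, every allowed lag and coding (continuous, and banded
categorical where cut-points are configured) is fitted univariately; the
variant with the lowest p-value on a dispersion-scaled F test against the
null wins, with ties broken by smaller lag, then continuous before
categorical. (ii) All subsets of the winners (shortlist capped at 8) are
ranked by in-sample district-level DSS. (iii) The top candidates are
re-ranked by mean DSS on district-grouped k-fold cross-validation — grouping
by district, not household, is essential because the model's job is to
predict *unsurveyed* districts. Held-out districts are predicted at
population level (without their random intercepts), and predictions are
summed to district level with predictive variance \(\phi \mu\). (iv) Allowed
pairwise interactions among selected main effects are kept if they improve
CV-DSS. (v) The random-intercept refit is retained if its CV-DSS is lower.
Tie-breaks always favour fewer terms, then lexicographic order, so selection
is deterministic for fixed data.

## Counterfactuals and the bootstrap

A scenario substitutes per-district reference values for each model
predictor (reference-window means, series means or minima, baseline-period
means, or fixed values) and retains a fraction of observed displacement when
denominators are rebuilt (5% in the most likely scenario — displacement not
attributable to the crisis — 20% in the reasonable worst case, 0 in the best
case). The packaged `default_scenarios()` use series means/minima because the
synthetic predictors are generic; a domain analysis should encode its own
reference windows.

For each stratum the model gives \(m\) (log rate, per-10,000-person-day
scale) and fixed-effect standard error \(s\); tolls are
\(\exp(N(m, s)) \times \text{person-days} / 10^4\) over \(n\) draws. Points
are medians, intervals 2.5th/97.5th percentiles. Design choices worth
stating:

* **Model error only.** \(s\) uses the fixed-effect covariance; no random
  effect or dispersion-forecast inflation, and no denominator or sampling
  uncertainty is propagated.
* **`u_hat` in both arms.** The predicted district intercept enters observed
  *and* counterfactual predictions, so excess isolates predictor and
  denominator differences.
* **Common random numbers.** Observed and counterfactual draws share one
  standard-normal stream per stratum, variance-reducing their difference;
  identical scenarios give excess exactly 0 (0 to 0).
* **Aggregate-then-summarise.** Group draws are draw-wise sums, so group
  point estimates are not generally sums of stratum medians; tolls are
  rounded to the nearest 100 (rates to two decimals) at report time only.

## The synthetic crisis generator

`sim_config()` / `simulate_crisis()` generate a ground-truth surface
\( \text{rate} = \text{rate}_0\, e^{X\beta + u} \) with AR(1) predictor
series, then sample surveys, population sources and displacement flows from
it. Defaults describe the study conditions the pipeline is meant for:
baseline CDR 0.55 and U5DR 1.14 per 10,000 person(child)-days, households of
5.3 members on average with 19% under 5, 35% of under-5 deaths among
infants, recall periods of 90–180 days, crude birth rate 33.7 per 1,000
person-years with net out-migration, district populations lognormal around
190,000, growth 0.25%/month, and ~0.4%/month displacement of which 10%
crosses the external border. Households experience the day-weighted mean
*log* rate over their recall window — the generative mirror of averaging
predictors over the recall period — and death counts are Poisson given that
rate, optionally multiplied by a mean-1 gamma frailty to force
overdispersion. Predictor missingness is completely at random, applied only
to the emitted tables (the truth surface stays complete).

What the generator does *not* emulate: spatially correlated violence,
settlement geography, respondent recall bias, survey nonresponse, or aging
of children across the recall window (membership class is fixed at the
survey date; with recalls under a year the error is second order). Passing
recovery tests on synthetic data therefore demonstrates the statistical
machinery is correct, not that any real-world dataset is unbiased.

## Numerical notes

* **Problem sizes.** The packaged recovery study uses 100 replicates of a
  40-district x 36-month crisis surveyed by 40 surveys of 25 clusters x 20
  households, chosen to give ~800 deaths per replicate and Monte-Carlo
  standard errors near 2 percentage points on coverage; the acceptance
  script runs a 20-district end-to-end pipeline and a 40-replicate recovery
  study at 15 districts.
* **Coverage study conditions.** The recovery study runs with unit
  robustness weights and no random intercept: sub-unit prior weights make
  the Pearson statistic estimate roughly `mean(weight) < 1`, and the floor
  at 1 then over-inflates intervals. Weight semantics (weight 0 equals
  deletion) and \(\sigma_u^2\) recovery are verified separately.
* **Dispersion at tiny expected counts.** Because the midpoint convention
  credits a death's own half-period of exposure, the offset is mildly
  outcome-dependent; with household expected counts near 0.04 this deflates
  the Pearson dispersion to ~0.9 for genuinely Poisson counts. The
  Poisson-dispersion check therefore conditions on the generative exposure,
  and the frailty stress test is run where dispersion is identifiable
  (frailty variance 6 at catastrophic-emergency rates and 150–250-day
  recalls, so variance x expected count ~ 1).
* **Banding convention.** Categorical bands are right-open: a value equal to
  a cut-point joins the upper band, everywhere.
* **Lag-then-impute.** Lags are computed on imputed series, then the leading
  lag months are re-imputed, so the analysis window keeps full support;
  recall averaging weights partial months by day overlap (an unweighted
  month-mean variant is available via `day_weighted = FALSE`).
* **Degenerate inputs.** Zero person-time rows are dropped with a warning;
  all-grade-zero denominators, all-missing series, collinear designs,
  out-of-horizon flows and negative populations are errors naming the
  offending field or stratum; a random-intercept variance pinned at zero
  returns the fixed-equivalent fit with a notice.
* **Determinism.** One pipeline seed is split into named substreams (truth,
  surveys, population, missingness, CV folds, bootstrap per outcome), so a
  fixed configuration reproduces the full report bundle bit for bit, and
  sensitivity runs differ from baseline only through the scenario.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, n_lgas = 12, n_months = 24, n_surveys = 24,
                  clusters_per_survey = 10, households_per_cluster = 10)
sim <- simulate_crisis(cfg)
pc <- pipeline_config(sim$households, sim$surveys, sim$predictors,
                      sim$sources, sim$flows, lga_states = sim$lga_states,
                      outcomes = "cdr", max_lag = 2, k = 5, top_k = 3,
                      n_draws = 200, seed = 7, mixed = FALSE)
run_pipeline(pc)
```

## Known limitations

The module contracts are generic where the original study context was
specific: the denominator module does not encode any particular country's
source-grading rubric or growth rates, and quality scores are inputs rather
than computed from a rubric. Survey design effects are not modelled (the
model consumes household rows directly). Cause-of-death analysis is limited
to an optional injury flag. Uncertainty from denominators and survey
sampling is deliberately not propagated, so intervals should be read as
model error only.
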