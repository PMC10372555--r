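# Bias sensitivity analyses: denominator bias (population and IDP figures),
# under-5 death under-ascertainment, and inflation of death rates in
# inaccessible strata.

#' Define a bias scenario
#'
#' @param kind one of `"population_ratio"` (ratio of actual to observed
#'   population, allowed 0.7-1.3), `"idp_ratio"` (ratio of actual to observed
#'   IDP figures, 0.5-1.5), `"child_underascertainment"` (fraction of under-5
#'   deaths missed by surveys, 0-0.5) or `"inaccessible_inflation"`
#'   (multiplier on true death rates in partially/inaccessible strata, 1-2).
#' @param value the scenario value, within the kind's allowed range.
#' @return an object of class `bias_scenario`.
#' @export
bias_scenario <- function(kind, value) {
  ranges <- list(population_ratio = c(0.7, 1.3),
                 idp_ratio = c(0.5, 1.5),
                 child_underascertainment = c(0, 0.5),
                 inaccessible_inflation = c(1, 2))
  if (!kind %in% names(ranges)) stop("unknown bias scenario kind: ", kind, call. = FALSE)
  r <- ranges[[kind]]
  if (value < r[1] || value > r[2]) {
    stop(sprintf("%s value %.3g outside allowed range [%g, %g]", kind, value, r[1], r[2]),
         call. = FALSE)
  }
  structure(list(kind = kind, value = value), class = "bias_scenario")
}

#' Rebuild denominators under a population or IDP bias scenario
#'
#' Repeats the denominator reconstruction with the biased figures, so every
#' downstream quantity (per-capita predictors, person-time, tolls) shifts
#' with the scenario. A population ratio multiplies the final totals; an IDP
#' ratio rescales the displacement flows before totals are rebuilt.
#'
#' @param scenario a [bias_scenario()] of kind `population_ratio` or
#'   `idp_ratio`.
#' @param sources,flows,months,... passed through to [build_denominators()].
#' @return a denominator series data frame.
#' @export
rescale_denominators <- function(scenario, sources, flows, months, ...) {
  stopifnot(inherits(scenario, "bias_scenario"))
  switch(scenario$kind,
    population_ratio = build_denominators(sources, flows, months, ...,
                                          population_ratio = scenario$value),
    idp_ratio = build_denominators(sources, flows, months, ...,
                                   idp_ratio = scenario$value),
    stop("rescale_denominators needs a population_ratio or idp_ratio scenario",
         call. = FALSE))
}

#' Correct under-5 death counts for under-ascertainment
#'
#' If a fraction `p` of under-5 deaths was missed, the expected complete
#' count is the observed count divided by `1 - p`; the correction is applied
#' as an expected-count scaling of `deaths_under5` (and `deaths_all` by the
#' added under-5 deaths) before refitting the U5DR model.
#'
#' @param records household records.
#' @param p fraction of under-5 deaths missed, in `[0, 0.5]`.
#' @return the records with scaled (possibly non-integer) under-5 death
#'   counts.
#' @export
inflate_child_deaths <- function(records, p) {
  if (p < 0 || p > 0.5) stop("missed fraction p must lie in [0, 0.5]", call. = FALSE)
  if (p == 0) return(records)
  added <- records$deaths_under5 * (1 / (1 - p) - 1)
  records$deaths_under5 <- records$deaths_under5 + added
  records$deaths_all <- records$deaths_all + added
  records
}

#' Inflate predicted death rates in inaccessible strata
#'
#' Shifts the stratum log rate `m` by `log(factor)` wherever humanitarian
#' accessibility is partial or none, leaving fully accessible strata
#' untouched; the bootstrap and aggregation are then re-run on the shifted
#' predictions.
#'
#' @param predictions stratum prediction data frame with columns `m` and `s`.
#' @param accessibility character vector per stratum, `"full"` or
#'   `"partial_or_none"`.
#' @param factor rate multiplier in `[1, 2]`.
#' @return the predictions with shifted `m`.
#' @export
inflate_inaccessible <- function(predictions, accessibility, factor) {
  if (factor < 1 || factor > 2) stop("inflation factor must lie in [1, 2]", call. = FALSE)
  if (length(accessibility) != nrow(predictions) || anyNA(accessibility)) {
    stop("accessibility flags missing for some strata", call. = FALSE)
  }
  flagged <- accessibility == "partial_or_none"
  predictions$m[flagged] <- predictions$m[flagged] + log(factor)
  predictions
}
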