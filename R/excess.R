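# Counterfactual scenario construction, per-stratum mortality prediction,
# the parametric lognormal bootstrap of death tolls, and draw-wise
# aggregation of tolls and excess.

#' Define a counterfactual scenario
#'
#' A scenario substitutes no-crisis values for each model predictor and
#' retains a fraction of the observed displacement when denominators are
#' rebuilt. Predictor rules are per-variable lists with a `type`:
#' * `"window_mean"` — per LGA, the mean of the series over reference months
#'   (`months`), e.g. pre- and post-inflation price windows;
#' * `"series_mean"` — per LGA, the mean of the whole series;
#' * `"series_min"` — per LGA, the minimum of the whole series;
#' * `"baseline"` — per LGA, the mean of the first `k` months (e.g.
#'   humanitarian presence before scale-up);
#' * `"fixed"` — a constant `value` for all strata;
#' * `"observed"` — leave the variable untouched.
#'
#' @param name scenario name (`"observed"`, `"most_likely"`,
#'   `"reasonable_worst"`, `"reasonable_best"`, or custom).
#' @param predictor_rules named list of rules, one per ruled variable.
#' @param displacement_retention fraction of observed displacement flows kept
#'   under the scenario, in `[0, 1]` (e.g. 0.05 for displacement not caused
#'   by the crisis, 0 for none).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, predictor_rules = list(), displacement_retention = 1) {
  stopifnot(displacement_retention >= 0, displacement_retention <= 1)
  for (v in names(predictor_rules)) {
    type <- predictor_rules[[v]]$type
    if (!type %in% c("window_mean", "series_mean", "series_min", "baseline",
                     "fixed", "observed")) {
      stop("unknown rule type '", type, "' for variable ", v, call. = FALSE)
    }
  }
  structure(list(name = name, predictor_rules = predictor_rules,
                 displacement_retention = displacement_retention),
            class = "scenario_spec")
}

#' Apply a scenario's predictor rules to an observed predictor frame
#'
#' Each ruled variable's values are replaced, per LGA, by the scalar the rule
#' prescribes; unruled variables pass through unchanged.
#'
#' @param frame long predictor frame (`variable`, `lga_id`, `month`, `value`)
#'   under observed conditions.
#' @param scenario a [scenario_spec()].
#' @return the counterfactual frame, same shape.
#' @export
build_scenario_data <- function(frame, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  out <- frame
  for (v in names(scenario$predictor_rules)) {
    rule <- scenario$predictor_rules[[v]]
    if (rule$type == "observed") next
    sel_v <- out$variable == v
    if (!any(sel_v)) stop("rule references unknown variable ", v, call. = FALSE)
    for (g in unique(out$lga_id[sel_v])) {
      sel <- sel_v & out$lga_id == g
      x <- out$value[sel]
      months <- out$month[sel]
      repl <- switch(rule$type,
        window_mean = {
          missing_m <- setdiff(rule$months, months)
          if (length(missing_m)) {
            stop("scenario '", scenario$name, "' references months absent from the frame: ",
                 paste(missing_m, collapse = ", "), call. = FALSE)
          }
          mean(x[months %in% rule$months])
        },
        series_mean = mean(x),
        series_min = min(x),
        baseline = mean(x[order(months)][seq_len(min(rule$k, length(x)))]),
        fixed = rule$value)
      out$value[sel] <- repl
    }
  }
  out
}

#' Predict a stratum's log death rate and its standard error
#'
#' `m` is the log rate on the per-10,000-person-day scale,
#' `x'beta + u + log(10^4)`; `s` is the fixed-effect Wald standard error of
#' the linear predictor.
#'
#' @param model a `rate_model`.
#' @param covariates one row of covariate values per stratum.
#' @param lga LGA id per stratum (for the random intercept, if present).
#' @param include_u include `u_hat` in `m` (used for both observed and
#'   counterfactual predictions, so excess isolates predictor and denominator
#'   differences).
#' @return data frame with columns `m` and `s`.
#' @export
predict_stratum <- function(model, covariates = NULL, lga = NULL, include_u = TRUE) {
  pr <- predict_log_rate(model, covariates, lga = lga, include_u = include_u)
  data.frame(m = pr$m + log(1e4), s = pr$s)
}

#' Parametric bootstrap of stratum death tolls
#'
#' For each stratum draws `n` values from `Normal(m, s)` on the log-rate
#' scale, exponentiates, and multiplies by person-time:
#' `toll = exp(N(m, s)) * person_days / 10000`. The point estimate is the
#' median of the draws and the 95% CI their 2.5th/97.5th percentiles; with
#' `s = 0` every draw equals `exp(m) * person_days / 10000` exactly.
#'
#' @param m,s,person_days stratum vectors: log rate (per 10,000 person-days),
#'   its SE (`>= 0`) and the stratum person-time (`>= 0`).
#' @param n number of draws (default 1,000).
#' @param seed RNG seed (ignored when `z` is supplied).
#' @param z optional matrix of standard-normal draws (strata x n); supplying
#'   the same `z` to observed and counterfactual scenarios pairs their draws
#'   on a common random-number stream, variance-reducing the excess.
#' @return list of class `toll_draws`: `draws` (strata x n matrix) and
#'   `summary` (`m`, `s`, `person_days`, `point`, `ci_low`, `ci_high`).
#' @export
bootstrap_tolls <- function(m, s, person_days, n = 1000, seed = 1, z = NULL) {
  S <- length(m)
  stopifnot(length(s) == S, length(person_days) == S,
            all(s >= 0), all(person_days >= 0))
  if (is.null(z)) {
    set.seed(seed)
    z <- matrix(stats::rnorm(S * n), nrow = S, ncol = n)
  }
  stopifnot(nrow(z) == S, ncol(z) == n)
  draws <- exp(m + s * z) * person_days / 1e4
  structure(list(draws = draws, summary = cbind(
    data.frame(m = m, s = s, person_days = person_days),
    draw_quantiles(draws))), class = "toll_draws")
}

draw_quantiles <- function(draws) {
  q <- t(apply(draws, 1, stats::quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(point = q[, 1], ci_low = q[, 2], ci_high = q[, 3])
}

#' Aggregate stratum toll draws by group
#'
#' Draws are summed draw-wise within groups (state, year, overall), then
#' summarised: the point estimate is the median of the summed draws, the 95%
#' CI their 2.5th/97.5th percentiles. Aggregation before summarisation means
#' group estimates are not generally the sum of stratum point estimates.
#'
#' @param tolls a `toll_draws` object.
#' @param group grouping vector, one per stratum (a constant aggregates
#'   everything).
#' @return a `toll_draws` with one row per group and a `group` column in the
#'   summary.
#' @export
aggregate_draws <- function(tolls, group) {
  stopifnot(inherits(tolls, "toll_draws"), length(group) == nrow(tolls$draws))
  draws <- rowsum(tolls$draws, group = group, reorder = TRUE)
  structure(list(draws = draws,
                 summary = cbind(data.frame(group = rownames(draws)),
                                 draw_quantiles(draws))),
            class = "toll_draws")
}

#' Excess mortality from paired observed and counterfactual draws
#'
#' Draw-wise difference (observed minus counterfactual), summarised like any
#' toll: median and percentile CI of the differences. Negative excess is
#' permitted (a counterfactual may exceed observed mortality).
#'
#' @param observed,counterfactual `toll_draws` objects with identical
#'   dimensions and row order.
#' @return a `toll_draws` of excess deaths.
#' @export
excess_from_draws <- function(observed, counterfactual) {
  stopifnot(inherits(observed, "toll_draws"), inherits(counterfactual, "toll_draws"))
  if (!identical(dim(observed$draws), dim(counterfactual$draws)) ||
      !identical(rownames(observed$draws), rownames(counterfactual$draws))) {
    stop("observed and counterfactual draws are not paired", call. = FALSE)
  }
  draws <- observed$draws - counterfactual$draws
  keep <- intersect(c("group", "m", "s", "person_days"), names(observed$summary))
  structure(list(draws = draws,
                 summary = cbind(observed$summary[, keep, drop = FALSE],
                                 draw_quantiles(draws))),
            class = "toll_draws")
}

#' @export
print.toll_draws <- function(x, ...) {
  cat(sprintf("<toll_draws> %d strata x %d draws\n", nrow(x$draws), ncol(x$draws)))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Period-average death rate from toll draws
#'
#' Computed draw-wise as `10^4 * sum(tolls) / sum(person_days)` so the
#' toll/denominator identity holds exactly for every draw.
#'
#' @param tolls a stratum-level `toll_draws` (summary must carry
#'   `person_days`).
#' @param group optional grouping vector.
#' @return data frame of rate point estimates and 95% CIs per group, in
#'   deaths per 10,000 person-days.
#' @export
rate_from_draws <- function(tolls, group = NULL) {
  stopifnot(inherits(tolls, "toll_draws"), "person_days" %in% names(tolls$summary))
  if (is.null(group)) group <- rep("overall", nrow(tolls$draws))
  num <- rowsum(tolls$draws, group, reorder = TRUE)
  den <- rowsum(tolls$summary$person_days, group, reorder = TRUE)
  rates <- 1e4 * num / as.vector(den)
  cbind(data.frame(group = rownames(num)), draw_quantiles(rates))
}
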