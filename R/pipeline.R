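# End-to-end pipeline driver: schema validation, the six estimation steps,
# report tables and delimited I/O.

input_schemas <- list(
  households = c("survey_id", "cluster_id", "lga_id", "n_current_members",
                 "n_current_under5", "deaths_all", "deaths_under5",
                 "deaths_infant", "deaths_injury", "births", "arrivals",
                 "departures"),
  surveys = c("survey_id", "lga_id", "recall_start", "recall_end",
              "recall_days", "quality_score", "sampling_coverage",
              "robustness_weight", "flag_incomplete", "flag_implausible"),
  predictors = c("variable", "lga_id", "month", "value"),
  sources = c("source_id", "lga_id", "reference_date", "population",
              "quality_grade", "monthly_growth"),
  flows = c("month", "from_lga", "to_lga", "persons"))

#' Validate pipeline input tables against their schemas
#'
#' Checks required columns, value ranges and cross-field constraints
#' (non-negative counts, under-5 deaths not exceeding all-age deaths, infant
#' deaths not exceeding under-5 deaths, scores and weights in `[0, 1]`,
#' recall length consistent with its inclusive date window, positive
#' populations, grades in `(0, 1]`).
#'
#' @param tables named list with `households`, `surveys`, `predictors`,
#'   `sources`, `flows` data frames.
#' @param recall_bounds plausibility bounds on recall length in days.
#' @return data frame of violations (`table`, `row`, `column`, `message`);
#'   zero rows means all inputs validate.
#' @export
validate_inputs <- function(tables, recall_bounds = c(30, 366)) {
  v <- list()
  flag <- function(table, row, column, message) {
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row,
                                       column = column, message = message)
  }
  for (tb in names(input_schemas)) {
    if (is.null(tables[[tb]])) { flag(tb, NA, NA, "table missing"); next }
    miss <- setdiff(input_schemas[[tb]], names(tables[[tb]]))
    for (m in miss) flag(tb, NA, m, "required column missing")
  }
  hh <- tables$households
  if (!is.null(hh) && all(input_schemas$households %in% names(hh))) {
    counts <- c("n_current_members", "n_current_under5", "deaths_all",
                "deaths_under5", "deaths_infant", "births", "arrivals", "departures")
    for (cl in counts) {
      bad <- which(!is.na(hh[[cl]]) & hh[[cl]] < 0)
      for (r in bad) flag("households", r, cl, "negative count")
    }
    bad <- which(hh$deaths_under5 > hh$deaths_all)
    for (r in bad) flag("households", r, "deaths_under5", "exceeds deaths_all")
    bad <- which(!is.na(hh$deaths_infant) & hh$deaths_infant > hh$deaths_under5)
    for (r in bad) flag("households", r, "deaths_infant", "exceeds deaths_under5")
  }
  sv <- tables$surveys
  if (!is.null(sv) && all(input_schemas$surveys %in% names(sv))) {
    len <- as.numeric(as.Date(sv$recall_end) - as.Date(sv$recall_start)) + 1
    bad <- which(abs(len - sv$recall_days) > 0.5)
    for (r in bad) flag("surveys", r, "recall_days", "inconsistent with recall window")
    bad <- which(sv$recall_days < recall_bounds[1] | sv$recall_days > recall_bounds[2])
    for (r in bad) flag("surveys", r, "recall_days", "outside plausibility bounds")
    for (cl in c("quality_score", "sampling_coverage", "robustness_weight")) {
      bad <- which(sv[[cl]] < 0 | sv[[cl]] > 1)
      for (r in bad) flag("surveys", r, cl, "outside [0, 1]")
    }
    bad <- which(abs(sv$robustness_weight - sv$quality_score * sv$sampling_coverage) > 1e-6)
    for (r in bad) flag("surveys", r, "robustness_weight",
                        "not the product of quality score and sampling coverage")
  }
  pr <- tables$predictors
  if (!is.null(pr) && "month" %in% names(pr)) {
    bad <- which(!grepl("^\\d{4}-\\d{2}$", pr$month))
    for (r in bad) flag("predictors", r, "month", "not a YYYY-MM key")
  }
  so <- tables$sources
  if (!is.null(so) && all(input_schemas$sources %in% names(so))) {
    for (r in which(so$population <= 0)) flag("sources", r, "population", "not positive")
    bad <- which(so$quality_grade <= 0 | so$quality_grade > 1)
    for (r in bad) flag("sources", r, "quality_grade", "outside (0, 1]")
  }
  fl <- tables$flows
  if (!is.null(fl) && "persons" %in% names(fl)) {
    for (r in which(fl$persons < 0)) flag("flows", r, "persons", "negative flow")
  }
  if (length(v)) do.call(rbind, v) else {
    data.frame(table = character(), row = integer(), column = character(),
               message = character())
  }
}

#' Default counterfactual scenario set
#'
#' Generic no-crisis scenarios for arbitrary predictors: the most likely
#' scenario sets every model predictor to its per-LGA series mean and keeps
#' 5% of displacement (movements not caused by the crisis); the reasonable
#' worst case also uses series means but keeps 20% of displacement; the
#' reasonable best case uses per-LGA series minima and removes displacement
#' entirely. Domain analyses should replace these with variable-specific
#' rules (reference price windows, baseline humanitarian presence, and so
#' on) via [scenario_spec()].
#'
#' @param variables character vector of predictor variable names to rule.
#' @return named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function(variables) {
  rules <- function(type) {
    stats::setNames(lapply(variables, function(v) list(type = type)), variables)
  }
  list(most_likely = scenario_spec("most_likely", rules("series_mean"), 0.05),
       reasonable_worst = scenario_spec("reasonable_worst", rules("series_mean"), 0.20),
       reasonable_best = scenario_spec("reasonable_best", rules("series_min"), 0))
}

#' Assemble a pipeline configuration
#'
#' @param households,surveys,predictors,sources,flows input tables (see
#'   [validate_inputs()] for schemas).
#' @param lga_states optional LGA-to-state map (`lga_id`, `state_id`) for
#'   state-level aggregation.
#' @param accessibility optional accessibility flags per LGA-month.
#' @param window `c(first, last)` month keys of the analysis window; defaults
#'   to the predictor frame's range.
#' @param outcomes subset of `c("cdr", "u5dr")`.
#' @param max_lag maximum lag (months) explored per predictor; scalar or
#'   named per variable.
#' @param cut_points optional named list of cut-point vectors; a variable
#'   listed here is also screened in banded categorical form.
#' @param k,cap,top_k,interactions,mixed model-selection settings (see
#'   [select_model()]); `mixed = FALSE` skips the random-intercept stage.
#' @param n_draws,seed bootstrap draws per stratum and the single pipeline
#'   seed (split into per-module substreams).
#' @param under5_frac under-5 population fraction for denominators.
#' @param cdr_ceiling survey implausibility threshold (CDR per 10,000
#'   person-days).
#' @param scenarios named list of [scenario_spec()]; `NULL` for
#'   [default_scenarios()] over all predictor variables.
#' @param sensitivity list of [bias_scenario()] objects to run after the main
#'   estimates.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(households, surveys, predictors, sources, flows,
                            lga_states = NULL, accessibility = NULL,
                            window = NULL, outcomes = c("cdr", "u5dr"),
                            max_lag = 3, cut_points = NULL,
                            k = 10, cap = 8, top_k = 5, interactions = NULL,
                            mixed = TRUE, n_draws = 1000, seed = 1,
                            under5_frac = 0.19, cdr_ceiling = 10,
                            scenarios = NULL, sensitivity = list()) {
  if (is.null(window)) window <- range(predictors$month)
  check_that(length(window) == 2 && window[1] <= window[2], "window", "must be non-empty")
  check_that(is.numeric(seed) && length(seed) == 1, "seed", "must be set")
  if (is.null(scenarios)) scenarios <- default_scenarios(unique(predictors$variable))
  structure(list(households = households, surveys = surveys,
                 predictors = predictors, sources = sources, flows = flows,
                 lga_states = lga_states, accessibility = accessibility,
                 window = window, outcomes = match.arg(outcomes,
                                                       c("cdr", "u5dr"),
                                                       several.ok = TRUE),
                 max_lag = max_lag, cut_points = cut_points,
                 k = k, cap = cap, top_k = top_k, interactions = interactions,
                 mixed = mixed, n_draws = n_draws, seed = seed,
                 under5_frac = under5_frac, cdr_ceiling = cdr_ceiling,
                 scenarios = scenarios, sensitivity = sensitivity),
            class = "pipeline_config")
}

# lag-then-impute series for one variable, per LGA, over the window
variant_frame <- function(prep, variable, lag, months) {
  sub <- prep[prep$variable == variable & prep$month %in% months, , drop = FALSE]
  sub <- sub[order(sub$lga_id, sub$month), ]
  for (g in unique(sub$lga_id)) {
    sel <- sub$lga_id == g
    sub$value[sel] <- impute_series(lag_series(sub$value[sel], lag),
                                    label = paste(variable, g))
  }
  sub
}

# day-weighted recall-period mean of a variant series per survey
survey_covariate <- function(vf, surveys) {
  vapply(seq_len(nrow(surveys)), function(i) {
    sel <- vf$lga_id == surveys$lga_id[i]
    recall_mean(vf$value[sel], vf$month[sel],
                surveys$recall_start[i], surveys$recall_end[i])
  }, numeric(1))
}

#' Run the full estimation pipeline
#'
#' Executes the six steps in order for each requested outcome: (1) survey
#' reanalysis and exclusions, (2) denominator reconstruction, (3) predictor
#' preparation, (4) model selection, (5) observed and counterfactual
#' prediction with the toll bootstrap and aggregation by state, year and
#' overall, and (6) bias sensitivity analyses. All randomness derives from
#' the single configured seed, so a fixed configuration reproduces the
#' bundle exactly.
#'
#' @param config a [pipeline_config()].
#' @return a list (report bundle): `survey_summary`, `model_reports`,
#'   `estimates` (long table of tolls by outcome, measure, scenario and
#'   group, rounded to the nearest 100), `rates_by_year` (period CDR/U5DR per
#'   10,000 person-days, two decimals), `sensitivity`, `selection`, and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  viol <- validate_inputs(config)
  if (nrow(viol)) {
    stop("input validation failed: ",
         paste(sprintf("%s row %s column %s: %s", viol$table, viol$row,
                       viol$column, viol$message)[seq_len(min(5, nrow(viol)))],
               collapse = "; "), call. = FALSE)
  }
  months <- month_seq(config$window[1], config$window[2])

  ## step 1 — survey reanalysis
  svy <- config$surveys
  est <- do.call(rbind, lapply(seq_len(nrow(svy)), function(i) {
    rec <- config$households[config$households$survey_id == svy$survey_id[i], ]
    cbind(data.frame(survey_id = svy$survey_id[i]),
          estimate_rates(rec, svy$recall_days[i]))
  }))
  eligible <- apply_exclusions(svy, est, config$cdr_ceiling)
  hh <- config$households[config$households$survey_id %in% eligible$survey_id, ]
  est_el <- est[est$survey_id %in% eligible$survey_id, ]
  year <- format(as.Date(eligible$recall_end), "%Y")
  survey_summary <- summarize_surveys(est_el, group = year)

  ## step 2 — denominators
  den <- build_denominators(config$sources, config$flows, months,
                            under5_frac = config$under5_frac,
                            accessibility = config$accessibility)

  ## step 3 — predictor preparation (imputation; lags explored in selection)
  prep <- prepare_predictors(config$predictors)
  variables <- unique(prep$variable)

  hh_meta <- eligible[match(hh$survey_id, eligible$survey_id), ]
  pt <- person_time(hh, hh_meta$recall_days)
  weights <- hh_meta$robustness_weight

  max_lag_of <- function(v) {
    if (length(config$max_lag) == 1) config$max_lag else config$max_lag[[v]]
  }
  ## candidate variants: one per lag, continuous (plus banded if cut points given)
  variant_defs <- list()
  for (v in variables) {
    for (l in 0:max_lag_of(v)) {
      nm <- sprintf("%s.lag%d", v, l)
      variant_defs[[nm]] <- list(variable = v, lag = l, coding = "continuous")
      if (!is.null(config$cut_points[[v]])) {
        variant_defs[[paste0(nm, ".cat")]] <-
          list(variable = v, lag = l, coding = "categorical",
               cut_points = config$cut_points[[v]])
      }
    }
  }
  vframes <- lapply(variant_defs, function(d) {
    variant_frame(prep, d$variable, d$lag, months)
  })
  hh_covs <- lapply(names(variant_defs), function(nm) {
    d <- variant_defs[[nm]]
    x <- survey_covariate(vframes[[nm]], eligible)[match(hh$survey_id, eligible$survey_id)]
    if (d$coding == "categorical") categorize(x, d$cut_points) else x
  })
  names(hh_covs) <- names(variant_defs)

  estimates <- list()
  model_reports <- list()
  selection <- list()
  sens_rows <- list()
  rates_by_year <- list()
  year_of <- substr(den$month, 1, 4)
  state_of <- if (!is.null(config$lga_states)) {
    config$lga_states$state_id[match(den$lga_id, config$lga_states$lga_id)]
  } else rep("all", nrow(den))

  for (outcome in config$outcomes) {
    deaths <- if (outcome == "cdr") hh$deaths_all else hh$deaths_under5
    exposure <- if (outcome == "cdr") pt$person_days else pt$child_days
    keep <- exposure > 0
    variants_by_variable <- lapply(stats::setNames(variables, variables), function(v) {
      nms <- names(variant_defs)[vapply(variant_defs, function(d) d$variable == v, logical(1))]
      stats::setNames(lapply(nms, function(nm) {
        list(values = hh_covs[[nm]][keep], lag = variant_defs[[nm]]$lag,
             coding = variant_defs[[nm]]$coding, name = nm)
      }), nms)
    })
    sel <- select_model(variants_by_variable, deaths[keep], exposure[keep],
                        hh$lga_id[keep], weights = weights[keep],
                        k = config$k, seed = substream_seed(config$seed, "cv"),
                        cap = config$cap, top_k = config$top_k,
                        interactions = config$interactions,
                        mixed = config$mixed)
    selection[[outcome]] <- sel
    model_reports[[outcome]] <- list(
      rate_ratios = rate_ratios(sel$model),
      dss_cv = sel$cv$dss_cv, dss_cv_sd = sel$cv$dss_cv_sd,
      mse_cv = sel$cv$mse_cv, mse_cv_sd = sel$cv$mse_cv_sd,
      relative_bias = sel$cv$relative_bias,
      phi = sel$model$phi, sigma_u_sq = sel$model$sigma_u_sq,
      mixed_retained = sel$mixed_retained)

    ## stratum design under observed conditions: variant value at each LGA-month
    chosen <- lapply(sel$screen, function(s) s$variant)
    stratum_design <- function(frame) {
      cols <- lapply(names(chosen), function(v) {
        nm <- chosen[[v]]
        d <- variant_defs[[nm]]
        vf <- variant_frame(frame, d$variable, d$lag, months)
        x <- vf$value[match(paste(den$lga_id, den$month),
                            paste(vf$lga_id, vf$month))]
        if (d$coding == "categorical") categorize(x, d$cut_points) else x
      })
      stats::setNames(as.data.frame(cols), names(chosen))
    }
    design_obs <- stratum_design(prep)
    pd_outcome <- function(d) {
      if (outcome == "cdr") d$person_days else {
        d$population_under5 * vapply(d$month, days_in_month, integer(1))
      }
    }
    pred_obs <- predict_stratum(sel$model, design_obs, lga = den$lga_id)
    set.seed(substream_seed(config$seed, paste0("boot_", outcome)))
    z <- matrix(stats::rnorm(nrow(den) * config$n_draws), nrow = nrow(den))
    tolls_obs <- bootstrap_tolls(pred_obs$m, pred_obs$s, pd_outcome(den),
                                 n = config$n_draws, z = z)

    add_rows <- function(tolls, measure, scenario) {
      do.call(rbind, lapply(list(state = state_of, year = year_of,
                                 overall = rep("overall", nrow(den))),
                            function(g) {
        agg <- aggregate_draws(tolls, g)
        data.frame(outcome = outcome, measure = measure, scenario = scenario,
                   group = agg$summary$group,
                   point = round_toll(agg$summary$point),
                   ci_low = round_toll(agg$summary$ci_low),
                   ci_high = round_toll(agg$summary$ci_high))
      }))
    }
    estimates[[length(estimates) + 1L]] <- add_rows(tolls_obs, "total", "observed")
    rby <- rate_from_draws(tolls_obs, year_of)
    rby$outcome <- outcome
    rby[c("point", "ci_low", "ci_high")] <- round(rby[c("point", "ci_low", "ci_high")], 2)
    rates_by_year[[outcome]] <- rby

    cf_store <- list()
    for (sc_name in names(config$scenarios)) {
      sc <- config$scenarios[[sc_name]]
      cf_frame <- build_scenario_data(prep, sc)
      cf_flows <- config$flows
      cf_flows$persons <- cf_flows$persons * sc$displacement_retention
      cf_den <- build_denominators(config$sources, cf_flows, months,
                                   under5_frac = config$under5_frac,
                                   accessibility = config$accessibility)
      pred_cf <- predict_stratum(sel$model, stratum_design(cf_frame),
                                 lga = den$lga_id)
      tolls_cf <- bootstrap_tolls(pred_cf$m, pred_cf$s, pd_outcome(cf_den),
                                  n = config$n_draws, z = z)
      cf_store[[sc_name]] <- tolls_cf
      estimates[[length(estimates) + 1L]] <- add_rows(tolls_cf, "counterfactual", sc_name)
      estimates[[length(estimates) + 1L]] <-
        add_rows(excess_from_draws(tolls_obs, tolls_cf), "excess", sc_name)
    }

    ## step 6 — sensitivity
    overall_point <- function(tolls) {
      aggregate_draws(tolls, rep("overall", nrow(den)))$summary$point
    }
    for (bs in config$sensitivity) {
      if (bs$kind %in% c("population_ratio", "idp_ratio")) {
        den2 <- rescale_denominators(bs, config$sources, config$flows, months,
                                     under5_frac = config$under5_frac,
                                     accessibility = config$accessibility)
        t2 <- bootstrap_tolls(pred_obs$m, pred_obs$s, pd_outcome(den2),
                              n = config$n_draws, z = z)
      } else if (bs$kind == "inaccessible_inflation") {
        p2 <- inflate_inaccessible(pred_obs, den$accessibility, bs$value)
        t2 <- bootstrap_tolls(p2$m, p2$s, pd_outcome(den),
                              n = config$n_draws, z = z)
      } else { # child_underascertainment
        if (outcome != "u5dr") next
        hh2 <- inflate_child_deaths(hh, bs$value)
        d2 <- hh2$deaths_under5[keep]
        fit2 <- if (!is.null(sel$model$sigma_u_sq)) {
          fit_random_intercept(d2, exposure[keep], hh$lga_id[keep],
                               data = sel$data, terms = sel$terms,
                               weights = weights[keep])
        } else {
          fit_quasipoisson(d2, exposure[keep], data = sel$data,
                           terms = sel$terms, weights = weights[keep])
        }
        pr2 <- predict_stratum(fit2, design_obs, lga = den$lga_id)
        t2 <- bootstrap_tolls(pr2$m, pr2$s, pd_outcome(den),
                              n = config$n_draws, z = z)
      }
      ml <- cf_store[["most_likely"]]
      sens_rows[[length(sens_rows) + 1L]] <- data.frame(
        outcome = outcome, kind = bs$kind, value = bs$value,
        total = round_toll(overall_point(t2)),
        excess = if (!is.null(ml)) {
          round_toll(aggregate_draws(excess_from_draws(t2, ml),
                                     rep("overall", nrow(den)))$summary$point)
        } else NA_real_)
    }
  }

  bundle <- list(
    survey_summary = survey_summary,
    survey_estimates = est_el,
    eligible_surveys = eligible,
    denominators = den,
    model_reports = model_reports,
    selection = selection,
    estimates = do.call(rbind, estimates),
    rates_by_year = do.call(rbind, rates_by_year),
    sensitivity = if (length(sens_rows)) do.call(rbind, sens_rows) else NULL,
    log = list(seed = config$seed, n_draws = config$n_draws,
               window = config$window, outcomes = config$outcomes,
               n_surveys_eligible = nrow(eligible),
               n_households = nrow(hh),
               runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               r_version = as.character(getRversion())))
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d eligible surveys, %d households; outcomes: %s\n",
              x$log$n_surveys_eligible, x$log$n_households,
              paste(x$log$outcomes, collapse = ", ")))
  ov <- x$estimates[x$estimates$group == "overall", ]
  print(ov[, c("outcome", "measure", "scenario", "point", "ci_low", "ci_high")],
        row.names = FALSE)
  invisible(x)
}

#' Write synthetic-run input tables to a directory
#'
#' Emits the five delimited input tables (plus the LGA-state map) in exactly
#' the schemas [run_pipeline()] reads, so a synthetic run exercises the real
#' I/O path.
#'
#' @param sim list with `households`, `surveys`, `sources`, `flows`,
#'   `predictors`, and optionally `lga_states`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_input_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("households", "surveys", "predictors", "sources", "flows",
               "lga_states")) {
    if (is.null(sim[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(sim[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read pipeline input tables from a directory
#'
#' @param dir directory holding the CSVs written by [write_input_tables()].
#' @return named list of data frames.
#' @export
read_input_tables <- function(dir) {
  out <- list()
  for (nm in c("households", "surveys", "predictors", "sources", "flows",
               "lga_states")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p)) {
      out[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
    } else if (nm != "lga_states") {
      stop("unreadable or missing input file: ", p, call. = FALSE)
    }
  }
  if (!is.null(out$surveys)) {
    out$surveys$recall_start <- as.Date(out$surveys$recall_start)
    out$surveys$recall_end <- as.Date(out$surveys$recall_end)
  }
  out
}

#' Write a report bundle as delimited tables
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(obj, p, row.names = FALSE)
    paths[name] <<- p
  }
  emit(bundle$survey_summary, "survey_summary")
  emit(bundle$estimates, "estimates")
  emit(bundle$rates_by_year, "rates_by_year")
  for (oc in names(bundle$model_reports)) {
    emit(bundle$model_reports[[oc]]$rate_ratios, paste0("rate_ratios_", oc))
  }
  if (!is.null(bundle$sensitivity)) emit(bundle$sensitivity, "sensitivity")
  writeLines(c(sprintf("seed: %s", bundle$log$seed),
               sprintf("draws: %s", bundle$log$n_draws),
               sprintf("window: %s to %s", bundle$log$window[1], bundle$log$window[2]),
               sprintf("eligible surveys: %s", bundle$log$n_surveys_eligible),
               sprintf("households: %s", bundle$log$n_households),
               sprintf("runtime_s: %.1f", bundle$log$runtime_s),
               sprintf("R: %s", bundle$log$r_version)),
             file.path(dir, "run_log.txt"))
  invisible(paths)
}

#' Simulate a crisis and write its pipeline inputs
#'
#' Convenience wrapper chaining [generate_truth()], [simulate_surveys()] and
#' [simulate_population()], returning everything [pipeline_config()] needs
#' (and the truth surface for recovery checks).
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, input tables are also written
#'   there via [write_input_tables()].
#' @return list: `surface`, `households`, `surveys`, `predictors` (with the
#'   configured missingness applied), `sources`, `flows`, `lga_states`.
#' @export
simulate_crisis <- function(config, dir = NULL) {
  surface <- generate_truth(config)
  svy <- simulate_surveys(surface, config)
  pop <- simulate_population(config)
  pred <- surface$predictors
  if (config$missing_frac > 0) {
    set.seed(substream_seed(config$seed, "missingness"))
    pred$value[stats::runif(nrow(pred)) < config$missing_frac] <- NA_real_
    # guarantee >= 2 observed values per series for imputation
    for (v in unique(pred$variable)) {
      for (g in unique(pred$lga_id)) {
        sel <- which(pred$variable == v & pred$lga_id == g)
        nobs <- sum(!is.na(pred$value[sel]))
        if (nobs < 2) {
          fill <- sel[is.na(pred$value[sel])][seq_len(2 - nobs)]
          pred$value[fill] <- surface$predictors$value[fill]
        }
      }
    }
  }
  sim <- list(surface = surface, households = svy$households,
              surveys = svy$surveys, predictors = pred,
              sources = pop$sources, flows = pop$flows,
              lga_states = surface$lgas)
  if (!is.null(dir)) write_input_tables(sim, dir)
  sim
}
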