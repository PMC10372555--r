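# Synthetic crisis generator: a known log-linear mortality surface with a
# district (LGA) random intercept, plus simulated cluster surveys, population
# sources and displacement flows with the statistical structure the estimation
# pipeline assumes.

#' Configuration for the synthetic crisis generator
#'
#' Bundles every tunable of the generator into a validated list. Defaults
#' describe a mid-sized protracted crisis: a baseline crude death rate (CDR)
#' of 0.55 and under-5 death rate (U5DR) of 1.14 per 10,000 person(child)-days,
#' households averaging 5.3 members of whom 19% are under 5, surveys with
#' recall periods of 90-180 days, and first-order autocorrelated district-month
#' predictor series.
#'
#' @param seed integer seed; every generator operation derives its own
#'   substream from it, so a fixed config reproduces outputs bit for bit.
#' @param n_lgas,n_months,first_month spatial/temporal extent of the surface;
#'   months are keyed `"YYYY-MM"` starting at `first_month`.
#' @param n_states number of states the LGAs are partitioned into.
#' @param n_surveys,clusters_per_survey,households_per_cluster survey design;
#'   each survey samples a single LGA as its universe.
#' @param recall_range integer min/max recall period in days; must lie within
#'   90 to 309 days.
#' @param cdr0,u5dr0 baseline death rates at predictor value 0 and random
#'   intercept 0, per 10,000 person-days (child-days for `u5dr0`).
#' @param beta named numeric vector of log rate-ratios per unit of each
#'   continuous predictor (applied to both outcomes unless `beta_u5` given).
#' @param beta_u5 optional separate coefficient vector for the U5DR surface.
#' @param sigma_u_sq variance of the centred-normal LGA random intercept on
#'   the log-rate scale.
#' @param frailty_var variance of a mean-1 gamma frailty multiplying each
#'   household's expected deaths; 0 gives pure Poisson counts, positive values
#'   produce the overdispersion (phi > 1) a quasi-likelihood fit must absorb.
#' @param predictor_rho,predictor_sd AR(1) autocorrelation and marginal SD of
#'   each predictor series per LGA.
#' @param missing_frac fraction of predictor values masked completely at
#'   random when the predictor table is emitted (the truth surface itself is
#'   always complete).
#' @param household_size_mean,prop_under5,prop_infant household composition:
#'   mean size, expected under-5 share of members, expected infant share of
#'   under-5 deaths.
#' @param birth_rate,arrival_rate,departure_rate demographic event rates per
#'   1,000 person-years.
#' @param cause_frac fraction of surveys that collect cause-of-death (injury)
#'   information; `injury_share` expected injury share of deaths in those.
#' @param injury_share see `cause_frac`.
#' @param mean_pop,pop_sdlog lognormal distribution of LGA baseline
#'   populations.
#' @param monthly_growth natural monthly population growth fraction.
#' @param displacement_rate expected fraction of an LGA's population displaced
#'   per month; `external_frac` of moves go to an external sink.
#' @param external_frac see `displacement_rate`.
#' @param under5_frac under-5 fraction applied to population denominators.
#' @param quality_range,coverage_range uniform ranges for survey quality score
#'   and sampling coverage (their product is the robustness weight).
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_truth()], [simulate_surveys()], [simulate_population()]
#' @export
sim_config <- function(seed = 1L,
                       n_lgas = 12L,
                       n_months = 24L,
                       first_month = "2016-01",
                       n_states = 3L,
                       n_surveys = 24L,
                       clusters_per_survey = 20L,
                       households_per_cluster = 15L,
                       recall_range = c(90L, 180L),
                       cdr0 = 0.55,
                       u5dr0 = 1.14,
                       beta = c(x1 = 0.18, x2 = -0.51, x3 = 0.83),
                       beta_u5 = NULL,
                       sigma_u_sq = 0.05,
                       frailty_var = 0,
                       predictor_rho = 0.8,
                       predictor_sd = 1,
                       missing_frac = 0.1,
                       household_size_mean = 5.3,
                       prop_under5 = 0.19,
                       prop_infant = 0.35,
                       birth_rate = 33.7,
                       arrival_rate = 80,
                       departure_rate = 122,
                       cause_frac = 0.35,
                       injury_share = 0.3,
                       mean_pop = 190000,
                       pop_sdlog = 0.5,
                       monthly_growth = 0.0025,
                       displacement_rate = 0.004,
                       external_frac = 0.1,
                       under5_frac = 0.19,
                       quality_range = c(0.6, 1),
                       coverage_range = c(0.7, 1)) {
  cfg <- as.list(environment())
  if (is.null(cfg$beta_u5)) cfg$beta_u5 <- cfg$beta
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos_int <- function(x) length(x) == 1 && is.numeric(x) && x >= 1 && x == round(x)
  check_that(pos_int(cfg$seed) || (is.numeric(cfg$seed) && cfg$seed == round(cfg$seed)),
             "seed", "must be an integer")
  for (f in c("n_lgas", "n_months", "n_states", "n_surveys",
              "clusters_per_survey", "households_per_cluster")) {
    check_that(pos_int(cfg[[f]]), f, "must be a positive integer")
  }
  check_that(cfg$n_states <= cfg$n_lgas, "n_states", "cannot exceed n_lgas")
  check_that(length(cfg$recall_range) == 2 &&
               cfg$recall_range[1] >= 90 && cfg$recall_range[2] <= 309 &&
               cfg$recall_range[1] <= cfg$recall_range[2],
             "recall_range", "must lie within [90, 309] days")
  for (f in c("cdr0", "u5dr0")) {
    check_that(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && is.finite(cfg[[f]]),
               f, "must be a finite non-negative rate")
  }
  check_that(is.numeric(cfg$beta) && !is.null(names(cfg$beta)) &&
               !anyNA(cfg$beta), "beta", "must be a named numeric vector")
  check_that(length(cfg$beta_u5) == length(cfg$beta),
             "beta_u5", "must match beta's length")
  check_that(cfg$sigma_u_sq >= 0, "sigma_u_sq", "must be non-negative")
  check_that(cfg$frailty_var >= 0, "frailty_var", "must be non-negative")
  for (f in c("missing_frac", "prop_under5", "prop_infant", "cause_frac",
              "injury_share", "external_frac", "under5_frac")) {
    check_that(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
  }
  check_that(abs(cfg$predictor_rho) < 1, "predictor_rho", "must be in (-1, 1)")
  check_that(grepl("^\\d{4}-\\d{2}$", cfg$first_month),
             "first_month", "must be a 'YYYY-MM' key")
  invisible(cfg)
}

# Independent RNG substream per generator operation: reproducible, and one
# operation's draws never shift another's.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000000L) * 2017L + h %% 100003L
}

sim_months <- function(cfg) month_seq(cfg$first_month, month_shift(cfg$first_month, cfg$n_months - 1L))
sim_lgas <- function(cfg) sprintf("lga%02d", seq_len(cfg$n_lgas))

#' Generate a known mortality surface
#'
#' Draws the ground truth the rest of the generator samples from: AR(1)
#' predictor series per LGA, a centred-normal LGA random intercept `u` with
#' variance `sigma_u_sq`, and log-linear CDR/U5DR surfaces
#' `rate = rate0 * exp(X beta + u)` in deaths per 10,000 person-days.
#'
#' @param config a [sim_config()].
#' @return an object of class `true_surface`: a list with `months`, `lgas`
#'   (LGA-to-state table), `u`, `beta`, `beta_u5`, `predictors` (complete
#'   long-format table: variable, lga_id, month, value) and `rates`
#'   (lga_id, month, true_cdr, true_u5dr).
#' @examples
#' surf <- generate_truth(sim_config(seed = 7, n_lgas = 4, n_months = 6))
#' head(surf$rates)
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "truth"))
  months <- sim_months(config)
  lgas <- sim_lgas(config)
  states <- sprintf("state%d", rep_len(seq_len(config$n_states), config$n_lgas))
  u <- stats::rnorm(config$n_lgas, 0, sqrt(config$sigma_u_sq))
  names(u) <- lgas

  vars <- names(config$beta)
  pred <- expand.grid(month = months, lga_id = lgas, variable = vars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pred <- pred[, c("variable", "lga_id", "month")]
  rho <- config$predictor_rho
  sd_m <- config$predictor_sd
  series <- function() {
    x <- numeric(config$n_months)
    x[1] <- stats::rnorm(1, 0, sd_m)
    innov_sd <- sd_m * sqrt(1 - rho^2)
    for (t in seq_len(config$n_months)[-1]) x[t] <- rho * x[t - 1] + stats::rnorm(1, 0, innov_sd)
    x
  }
  pred$value <- as.vector(replicate(length(vars) * config$n_lgas, series()))

  X <- matrix(pred$value, nrow = config$n_lgas * config$n_months,
              ncol = length(vars), dimnames = list(NULL, vars))
  key <- expand.grid(month = months, lga_id = lgas,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lin_cdr <- drop(X %*% config$beta) + u[key$lga_id]
  lin_u5 <- drop(X %*% config$beta_u5) + u[key$lga_id]
  rates <- data.frame(lga_id = key$lga_id, month = key$month,
                      true_cdr = config$cdr0 * exp(lin_cdr),
                      true_u5dr = config$u5dr0 * exp(lin_u5),
                      row.names = NULL)
  stopifnot(all(is.finite(rates$true_cdr)), all(is.finite(rates$true_u5dr)))
  structure(list(months = months,
                 lgas = data.frame(lga_id = lgas, state_id = states),
                 u = u, beta = config$beta, beta_u5 = config$beta_u5,
                 cdr0 = config$cdr0, u5dr0 = config$u5dr0,
                 predictors = pred, rates = rates),
            class = "true_surface")
}

#' @export
print.true_surface <- function(x, ...) {
  cat(sprintf("<true_surface> %d LGAs x %d months; CDR %.3g-%.3g per 10,000 person-days\n",
              nrow(x$lgas), length(x$months),
              min(x$rates$true_cdr), max(x$rates$true_cdr)))
  invisible(x)
}

# day-weighted mean of a per-month vector over a recall window
window_weights <- function(months, recall_start, recall_end) {
  w <- vapply(months, function(m) overlap_days(recall_start, recall_end, m), numeric(1))
  total <- as.numeric(as.Date(recall_end) - as.Date(recall_start)) + 1
  if (abs(sum(w) - total) > 1e-9) {
    stop("recall window extends outside the simulated month range", call. = FALSE)
  }
  w / sum(w)
}

#' Simulate cluster mortality surveys from a truth surface
#'
#' Emulates multistage cluster household surveys: each survey samples one LGA,
#' draws a recall window inside the surface's month range, and generates
#' household rosters and demographic events. A household's expected death
#' count is its true window rate times its person-time divided by 10,000;
#' the window rate is the exponential of the day-weighted mean log rate over
#' the recall period, so the generative model matches the analysis model's
#' recall-period predictor averaging. Counts are Poisson, optionally inflated
#' by a mean-1 gamma frailty (`frailty_var > 0`) to induce overdispersion.
#'
#' @param surface a [generate_truth()] result (true rates may be zero when the
#'   surface is constructed by hand, e.g. for null checks).
#' @param config the [sim_config()] used to build the surface.
#' @return a list with `households` (one row per household, the
#'   household-record schema) and `surveys` (one row per survey, the
#'   survey-metadata schema).
#' @export
simulate_surveys <- function(surface, config) {
  stopifnot(inherits(surface, "true_surface"), inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "surveys"))
  months <- surface$months
  lgas <- surface$lgas$lga_id
  first_day <- month_start(months[1])
  last_day <- month_end(months[length(months)])

  n_s <- config$n_surveys
  svy_lga <- c(rep_len(lgas, min(n_s, length(lgas))),
               if (n_s > length(lgas)) sample(lgas, n_s - length(lgas), replace = TRUE))
  recall_days <- sample(seq(config$recall_range[1], config$recall_range[2]), n_s, replace = TRUE)
  max_end <- as.integer(last_day - first_day) + 1L
  end_offset <- vapply(recall_days, function(r) sample(seq(r, max_end), 1L), integer(1))
  recall_end <- first_day + end_offset - 1L
  recall_start <- recall_end - recall_days + 1L
  quality <- stats::runif(n_s, config$quality_range[1], config$quality_range[2])
  coverage <- stats::runif(n_s, config$coverage_range[1], config$coverage_range[2])
  has_cause <- stats::runif(n_s) < config$cause_frac

  surveys <- data.frame(survey_id = sprintf("svy%03d", seq_len(n_s)),
                        lga_id = svy_lga,
                        recall_start = recall_start, recall_end = recall_end,
                        recall_days = recall_days,
                        quality_score = quality, sampling_coverage = coverage,
                        robustness_weight = quality * coverage,
                        flag_incomplete = FALSE, flag_implausible = FALSE)

  rate_tab <- surface$rates
  log_cdr <- log(pmax(rate_tab$true_cdr, .Machine$double.xmin))
  log_u5 <- log(pmax(rate_tab$true_u5dr, .Machine$double.xmin))
  rate_key <- paste(rate_tab$lga_id, rate_tab$month)

  hh_list <- vector("list", n_s)
  n_hh <- config$clusters_per_survey * config$households_per_cluster
  for (i in seq_len(n_s)) {
    w <- window_weights(months, recall_start[i], recall_end[i])
    idx <- match(paste(svy_lga[i], months), rate_key)
    cdr_i <- if (all(rate_tab$true_cdr[idx] == 0)) 0 else exp(sum(w * log_cdr[idx]))
    u5dr_i <- if (all(rate_tab$true_u5dr[idx] == 0)) 0 else exp(sum(w * log_u5[idx]))
    # over-5 rate chosen so the all-age rate marginally equals the CDR surface
    odr_i <- max((cdr_i - config$prop_under5 * u5dr_i) / (1 - config$prop_under5), 0)

    R <- recall_days[i]
    n_mem <- 1L + stats::rpois(n_hh, config$household_size_mean - 1)
    n_u5 <- stats::rbinom(n_hh, n_mem, config$prop_under5)
    py <- n_mem * R / 365
    births <- stats::rpois(n_hh, config$birth_rate / 1000 * py)
    arrivals <- stats::rpois(n_hh, config$arrival_rate / 1000 * py)
    departures <- stats::rpois(n_hh, config$departure_rate / 1000 * py)
    frail <- if (config$frailty_var > 0) {
      stats::rgamma(n_hh, shape = 1 / config$frailty_var, rate = 1 / config$frailty_var)
    } else rep(1, n_hh)
    child_pd <- n_u5 * R
    over_pd <- (n_mem - n_u5) * R + R / 2 * (births + arrivals + departures)
    deaths_u5 <- stats::rpois(n_hh, frail * u5dr_i * child_pd / 1e4)
    deaths_o5 <- stats::rpois(n_hh, frail * odr_i * over_pd / 1e4)
    deaths_all <- deaths_u5 + deaths_o5
    deaths_inf <- stats::rbinom(n_hh, deaths_u5, config$prop_infant)
    deaths_inj <- if (has_cause[i]) stats::rbinom(n_hh, deaths_all, config$injury_share) else NA_integer_

    hh_list[[i]] <- data.frame(
      survey_id = surveys$survey_id[i],
      cluster_id = sprintf("%s-c%02d", surveys$survey_id[i],
                           rep(seq_len(config$clusters_per_survey),
                               each = config$households_per_cluster)),
      lga_id = svy_lga[i],
      n_current_members = n_mem, n_current_under5 = n_u5,
      deaths_all = deaths_all, deaths_under5 = deaths_u5,
      deaths_infant = deaths_inf, deaths_injury = deaths_inj,
      births = births, arrivals = arrivals, departures = departures)
  }
  list(households = do.call(rbind, hh_list), surveys = surveys)
}

#' Simulate population sources and displacement flows
#'
#' Produces at least two graded point-in-time population sources per LGA
#' (distinct reference dates, quality grades in (0,1]) and a monthly
#' origin-destination table of displacement flows. Flows conserve people by
#' construction: every row moves `persons` from one LGA into another (or into
#' a single `"external"` sink standing in for refugee movements).
#'
#' @param config a [sim_config()].
#' @return a list with `sources` (source_id, lga_id, reference_date,
#'   population, quality_grade, monthly_growth) and `flows` (month, from_lga,
#'   to_lga, persons).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "population"))
  months <- sim_months(config)
  lgas <- sim_lgas(config)
  base <- stats::rlnorm(config$n_lgas, log(config$mean_pop) - config$pop_sdlog^2 / 2,
                        config$pop_sdlog)
  names(base) <- lgas

  src <- lapply(seq_along(lgas), function(i) {
    k <- sample(2:3, 1)
    ref_m <- sample(seq_along(months), k)
    data.frame(source_id = sprintf("%s-src%d", lgas[i], seq_len(k)),
               lga_id = lgas[i],
               reference_date = months[ref_m],
               population = round(base[i] * exp(stats::rnorm(k, 0, 0.05)) *
                                    (1 + config$monthly_growth)^(ref_m - 1)),
               quality_grade = round(stats::runif(k, 0.3, 1), 2),
               monthly_growth = config$monthly_growth)
  })
  sources <- do.call(rbind, src)
  rownames(sources) <- NULL

  flow_list <- list()
  if (config$displacement_rate > 0) {
    for (m in months) {
      n_out <- stats::rpois(config$n_lgas, config$displacement_rate * base)
      for (i in which(n_out > 0)) {
        dest <- if (stats::runif(1) < config$external_frac) "external" else {
          sample(setdiff(lgas, lgas[i]), 1)
        }
        flow_list[[length(flow_list) + 1L]] <- data.frame(
          month = m, from_lga = lgas[i], to_lga = dest, persons = n_out[i])
      }
    }
  }
  flows <- if (length(flow_list)) do.call(rbind, flow_list) else {
    data.frame(month = character(), from_lga = character(),
               to_lga = character(), persons = numeric())
  }
  list(sources = sources, flows = flows)
}
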