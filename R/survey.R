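# Reanalysis of SMART-style retrospective household mortality surveys:
# person-time accounting, demographic rate estimation, exclusion rules and
# multi-survey summaries.

#' Household person-time under the midpoint convention
#'
#' Each currently present household member contributes the full recall period;
#' every reported demographic event person (death, birth, arrival, departure)
#' contributes half of it, i.e. is treated as present from (or until) the
#' midpoint of the recall window. Child-time is computed analogously from
#' current under-5 membership and under-5 deaths.
#'
#' @param records data frame of household records (columns
#'   `n_current_members`, `n_current_under5`, `deaths_all`, `deaths_under5`,
#'   `births`, `arrivals`, `departures`).
#' @param recall_days length of the recall period in days (scalar or one per
#'   row).
#' @return data frame with columns `person_days` and `child_days`, one row per
#'   household.
#' @examples
#' person_time(data.frame(n_current_members = 5, n_current_under5 = 1,
#'                        deaths_all = 1, deaths_under5 = 0, births = 0,
#'                        arrivals = 0, departures = 0), recall_days = 100)
#' @export
person_time <- function(records, recall_days) {
  needed <- c("n_current_members", "n_current_under5", "deaths_all",
              "deaths_under5", "births", "arrivals", "departures")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  counts <- records[needed]
  if (any(vapply(counts, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    stop("negative counts in household records", call. = FALSE)
  }
  if (any(records$deaths_under5 > records$deaths_all)) {
    stop("deaths_under5 exceeds deaths_all", call. = FALSE)
  }
  R <- recall_days
  pd <- records$n_current_members * R +
    R / 2 * (records$deaths_all + records$births + records$arrivals + records$departures)
  cd <- records$n_current_under5 * R + R / 2 * records$deaths_under5
  if (any(pd < 0) || any(cd < 0)) {
    stop("negative person-time: more leavers than plausibly present", call. = FALSE)
  }
  data.frame(person_days = pd, child_days = cd)
}

#' Estimate demographic rates for one survey
#'
#' Pools households and computes the crude death rate (CDR, deaths per 10,000
#' person-days), under-5 death rate (U5DR, per 10,000 child-days), crude birth
#' rate (per 1,000 person-years), net migration rate (per 1,000 person-years;
#' may be negative), the infant share of under-5 deaths, and — when at least
#' `min_cause_coverage` of households carry cause-of-death data — the
#' injury-specific death rate.
#'
#' @param records household records for one survey.
#' @param recall_days recall period in days.
#' @param min_cause_coverage minimum fraction of households with non-missing
#'   `deaths_injury` for the injury rate to be reported (default 0.5).
#' @return one-row data frame: `cdr`, `u5dr`, `cbr`, `net_migration`,
#'   `injury_rate`, `prop_infant_deaths`, `person_days`, `child_days`,
#'   `deaths_all`, `deaths_under5`.
#' @examples
#' hh <- data.frame(n_current_members = 10, n_current_under5 = 2,
#'                  deaths_all = 2, deaths_under5 = 1, deaths_infant = 0,
#'                  deaths_injury = NA, births = 0, arrivals = 0,
#'                  departures = 0)
#' estimate_rates(hh[rep(1, 10), ], recall_days = 100)
#' @export
estimate_rates <- function(records, recall_days, min_cause_coverage = 0.5) {
  pt <- person_time(records, recall_days)
  pd <- sum(pt$person_days)
  cd <- sum(pt$child_days)
  if (pd <= 0) stop("zero total person-time: rates undefined", call. = FALSE)
  d_all <- sum(records$deaths_all)
  d_u5 <- sum(records$deaths_under5)
  d_inf <- if ("deaths_infant" %in% names(records)) sum(records$deaths_infant, na.rm = TRUE) else NA_real_
  py <- pd / 365
  cause_cov <- if ("deaths_injury" %in% names(records)) mean(!is.na(records$deaths_injury)) else 0
  injury <- if (cause_cov >= min_cause_coverage) {
    1e4 * sum(records$deaths_injury, na.rm = TRUE) / pd
  } else NA_real_
  data.frame(
    cdr = 1e4 * d_all / pd,
    u5dr = if (cd > 0) 1e4 * d_u5 / cd else NA_real_,
    cbr = 1000 * sum(records$births) / py,
    net_migration = 1000 * (sum(records$arrivals) - sum(records$departures)) / py,
    injury_rate = injury,
    prop_infant_deaths = if (d_u5 > 0) d_inf / d_u5 else NA_real_,
    person_days = pd, child_days = cd,
    deaths_all = d_all, deaths_under5 = d_u5)
}

#' Convert a per-10,000-person-day rate to per 1,000 person-years
#'
#' Humanitarian practice expresses death rates per 10,000 person-days;
#' demography per 1,000 person-years. The conversion is a factor of 36.5.
#'
#' @param rate_per_10k_pd numeric rate per 10,000 person-days.
#' @return rate per 1,000 person-years.
#' @examples
#' rate_per_1000py(0.55) # 20.075
#' @export
rate_per_1000py <- function(rate_per_10k_pd) rate_per_10k_pd * 36.5

#' Apply survey exclusion rules
#'
#' Drops surveys flagged as incomplete or implausible. The implausibility flag
#' may be refreshed from the survey's estimated CDR against a configurable
#' ceiling (default 10 deaths per 10,000 person-days, far beyond catastrophic
#' emergency levels). Each exclusion is reported via `message()`.
#'
#' @param surveys survey metadata (columns `survey_id`, `flag_incomplete`,
#'   `flag_implausible`).
#' @param estimates optional data frame with `survey_id` and `cdr`, used to
#'   set `flag_implausible` where `cdr > cdr_ceiling`.
#' @param cdr_ceiling implausibility threshold on CDR.
#' @return the eligible subset of `surveys`.
#' @export
apply_exclusions <- function(surveys, estimates = NULL, cdr_ceiling = 10) {
  if (!is.null(estimates)) {
    idx <- match(surveys$survey_id, estimates$survey_id)
    high <- !is.na(idx) & estimates$cdr[idx] > cdr_ceiling
    surveys$flag_implausible <- surveys$flag_implausible | high
  }
  out <- !surveys$flag_incomplete & !surveys$flag_implausible
  for (i in which(!out)) {
    reason <- if (surveys$flag_incomplete[i]) "incomplete dataset" else "implausible estimates"
    message(sprintf("excluding survey %s: %s", surveys$survey_id[i], reason))
  }
  if (!any(out)) warning("all surveys excluded", call. = FALSE)
  surveys[out, , drop = FALSE]
}

#' Summarise survey point estimates
#'
#' Reports, per indicator and group (typically the calendar year of the recall
#' midpoint), the median and 25th/75th percentiles of survey point estimates.
#'
#' @param estimates data frame of per-survey estimates.
#' @param group optional grouping vector (one per survey); `NULL` pools all.
#' @param indicators columns of `estimates` to summarise.
#' @return long data frame: `group`, `indicator`, `n`, `median`, `q25`, `q75`.
#' @export
summarize_surveys <- function(estimates,
                              group = NULL,
                              indicators = c("cdr", "u5dr", "cbr",
                                             "net_migration", "injury_rate",
                                             "prop_infant_deaths")) {
  indicators <- intersect(indicators, names(estimates))
  if (is.null(group)) group <- rep("overall", nrow(estimates))
  out <- list()
  for (g in unique(group)) {
    sub <- estimates[group == g, , drop = FALSE]
    if (!nrow(sub)) { warning("empty group ", g, call. = FALSE); next }
    for (ind in indicators) {
      v <- sub[[ind]][!is.na(sub[[ind]])]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(group = g, indicator = ind,
                                            n = length(v), median = q[2],
                                            q25 = q[1], q75 = q[3])
    }
  }
  do.call(rbind, out)
}
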