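# Reconstruction of LGA-month population denominators from graded
# point-in-time sources, growth projection and displacement flows.

#' Project a point-in-time population source to another month
#'
#' Compound growth: `population * (1 + monthly_growth)^k`, where `k` is the
#' signed number of months between the target month and the source's
#' reference month (backward projection uses a negative exponent).
#'
#' @param population persons at the reference date.
#' @param monthly_growth growth fraction per month.
#' @param reference_month,month `"YYYY-MM"` keys of the source reference date
#'   and the target month.
#' @return projected persons.
#' @examples
#' project_population(100000, 0.0025, "2016-01", "2017-01")
#' @export
project_population <- function(population, monthly_growth, reference_month, month) {
  stopifnot(population > 0)
  k <- month_diff(month, reference_month)
  population * (1 + monthly_growth)^k
}

#' Combine projected population sources by quality grade
#'
#' Grade-weighted arithmetic mean of the per-source projections.
#'
#' @param projections numeric vector of projected populations.
#' @param grades quality grades in (0, 1], same length.
#' @return persons.
#' @examples
#' combine_sources(c(100000, 200000), c(0.8, 0.2)) # 120000
#' @export
combine_sources <- function(projections, grades) {
  stopifnot(length(projections) == length(grades), length(projections) >= 1)
  if (all(grades == 0)) stop("all source quality grades are zero", call. = FALSE)
  stats::weighted.mean(projections, grades)
}

# cumulative net internal inflow and external (refugee) outflow per LGA-month
cumulate_flows <- function(flows, lgas, months) {
  net_in <- matrix(0, nrow = length(lgas), ncol = length(months),
                   dimnames = list(lgas, months))
  idp_in <- net_in
  if (nrow(flows)) {
    bad <- setdiff(flows$month, months)
    if (length(bad)) stop("flows reference months outside the horizon: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(flows))) {
      m <- flows$month[i]; n <- flows$persons[i]
      if (flows$from_lga[i] %in% lgas) {
        net_in[flows$from_lga[i], m] <- net_in[flows$from_lga[i], m] - n
      }
      if (flows$to_lga[i] %in% lgas) {
        net_in[flows$to_lga[i], m] <- net_in[flows$to_lga[i], m] + n
        idp_in[flows$to_lga[i], m] <- idp_in[flows$to_lga[i], m] + n
      }
    }
  }
  list(net_in = t(apply(net_in, 1, cumsum)), idp = t(apply(idp_in, 1, cumsum)))
}

#' Build the per-LGA-month denominator series
#'
#' For every LGA-month: projects each population source to the month, takes
#' the grade-weighted mean, then adds the cumulative net displacement inflow
#' (departures to the external sink count as refugee outflow). Under-5
#' population is a configured fraction of the total; person-days are the
#' population times the calendar month length.
#'
#' @param sources population source table (`lga_id`, `reference_date` as a
#'   month key, `population`, `quality_grade`, `monthly_growth`).
#' @param flows displacement flow table (`month`, `from_lga`, `to_lga`,
#'   `persons`); `to_lga = "external"` models refugee outflow.
#' @param months month keys of the analysis horizon.
#' @param under5_frac under-5 fraction of the population (scalar or named per
#'   LGA).
#' @param accessibility optional data frame (`lga_id`, `month`,
#'   `accessibility` in `{"full", "partial_or_none"}`); defaults to `"full"`.
#' @param idp_ratio,population_ratio bias multipliers used by the sensitivity
#'   module; 1 leaves the reconstruction unchanged.
#' @return data frame: `lga_id`, `month`, `population_total`,
#'   `population_under5`, `idp_count`, `person_days`, `accessibility`.
#' @export
build_denominators <- function(sources, flows, months, under5_frac = 0.19,
                               accessibility = NULL,
                               idp_ratio = 1, population_ratio = 1) {
  lgas <- sort(unique(sources$lga_id))
  cum <- cumulate_flows(flows, lgas, months)
  out <- expand.grid(month = months, lga_id = lgas,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("lga_id", "month")]
  base <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    s <- sources[sources$lga_id == out$lga_id[i], , drop = FALSE]
    proj <- mapply(project_population, s$population, s$monthly_growth,
                   s$reference_date, MoreArgs = list(month = out$month[i]))
    base[i] <- combine_sources(proj, s$quality_grade)
  }
  net <- cum$net_in[cbind(out$lga_id, out$month)] * idp_ratio
  idp <- cum$idp[cbind(out$lga_id, out$month)] * idp_ratio * population_ratio
  out$population_total <- (base + net) * population_ratio
  if (any(out$population_total < 0)) {
    bad <- out[out$population_total < 0, ][1, ]
    stop(sprintf("negative population for %s %s after displacement adjustment",
                 bad$lga_id, bad$month), call. = FALSE)
  }
  u5f <- if (length(under5_frac) == 1) rep(under5_frac, nrow(out)) else under5_frac[out$lga_id]
  out$population_under5 <- out$population_total * u5f
  out$idp_count <- pmin(idp, out$population_total)
  out$person_days <- out$population_total *
    vapply(out$month, days_in_month, integer(1))
  out$accessibility <- "full"
  if (!is.null(accessibility)) {
    idx <- match(paste(out$lga_id, out$month),
                 paste(accessibility$lga_id, accessibility$month))
    out$accessibility[!is.na(idx)] <- accessibility$accessibility[idx[!is.na(idx)]]
  }
  rownames(out) <- NULL
  out
}

#' Adjust a base population for cumulative displacement
#'
#' @param base persons before displacement adjustment.
#' @param cum_inflow cumulative IDP arrivals into the LGA up to the month.
#' @param cum_outflow cumulative departures (internal plus refugee) out of it.
#' @return adjusted persons.
#' @examples
#' apply_displacement(100000, 20000, 5000) # 115000
#' @export
apply_displacement <- function(base, cum_inflow, cum_outflow) {
  out <- base + cum_inflow - cum_outflow
  if (any(out < 0)) stop("negative population after displacement adjustment", call. = FALSE)
  out
}
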