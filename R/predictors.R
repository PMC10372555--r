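# Preparation of LGA-month predictor series: imputation, smoothing, lags,
# categorical banding, per-capita conversion, recall-period averaging.

#' Impute missing values in a monthly series
#'
#' Interior gaps are linearly interpolated in time; leading and trailing gaps
#' take the nearest observed value. Imputed values therefore never leave the
#' range of the neighbouring observations.
#'
#' @param x numeric series ordered by month (may contain `NA`).
#' @param label optional variable/LGA label for error messages.
#' @return the series with no missing values.
#' @examples
#' impute_series(c(1, NA, 3)) # 1 2 3
#' @export
impute_series <- function(x, label = "series") {
  if (all(is.na(x))) stop("all values missing in ", label, call. = FALSE)
  if (!anyNA(x)) return(x)
  idx <- seq_along(x)
  obs <- which(!is.na(x))
  out <- stats::approx(obs, x[obs], xout = idx, rule = 2)$y
  out
}

#' Trailing rolling mean
#'
#' Mean of the current and previous `window - 1` values; shorter at the start
#' of the series where fewer values are available.
#'
#' @param x numeric series.
#' @param window window length in months (1 = identity).
#' @return smoothed series, same length.
#' @export
rolling_mean <- function(x, window) {
  stopifnot(window >= 1)
  if (window == 1) return(x)
  vapply(seq_along(x), function(t) mean(x[max(1, t - window + 1):t]), numeric(1))
}

#' Lag a monthly series
#'
#' Value at month `t` becomes the value at month `t - lag`; the first `lag`
#' entries become missing (to be imputed or trimmed downstream).
#'
#' @param x numeric series ordered by month.
#' @param lag non-negative integer lag in months.
#' @param max_lag optional ceiling on the allowed lag for this variable.
#' @return lagged series, same length.
#' @export
lag_series <- function(x, lag, max_lag = NULL) {
  stopifnot(lag >= 0, lag == round(lag))
  if (!is.null(max_lag) && lag > max_lag) {
    stop(sprintf("lag %d exceeds the allowed maximum %d", lag, max_lag), call. = FALSE)
  }
  if (lag == 0) return(x)
  c(rep(NA_real_, min(lag, length(x))), utils::head(x, max(0, length(x) - lag)))
}

#' Convert a count to a per-100,000 population rate
#'
#' @param count events (e.g. humanitarian actors present, people killed).
#' @param population denominator population, must be positive.
#' @return rate per 100,000 population.
#' @examples
#' per_capita_rate(5, 100000) # 5
#' @export
per_capita_rate <- function(count, population) {
  if (any(population <= 0)) stop("zero or negative population denominator", call. = FALSE)
  1e5 * count / population
}

#' Band a continuous value into ordered categories
#'
#' Right-open intervals: a value equal to a cut-point joins the upper band.
#' Values below the first cut-point fall in the reference band.
#'
#' @param x numeric values.
#' @param cut_points strictly increasing interior cut-points.
#' @param labels optional band labels (`length(cut_points) + 1`); defaults to
#'   interval notation with the reference band first.
#' @return ordered factor of bands.
#' @examples
#' categorize(c(0.2, 0.25, 0.3, 0.4), cut_points = c(0.25, 0.35))
#' @export
categorize <- function(x, cut_points, labels = NULL) {
  if (is.unsorted(cut_points, strictly = TRUE)) {
    stop("cut_points must be strictly increasing", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- c(sprintf("<%g [ref.]", cut_points[1]),
                if (length(cut_points) > 1) {
                  sprintf("%g to <%g", utils::head(cut_points, -1), cut_points[-1])
                },
                sprintf(">=%g", cut_points[length(cut_points)]))
  }
  stopifnot(length(labels) == length(cut_points) + 1)
  cut(x, breaks = c(-Inf, cut_points, Inf), labels = labels,
      right = FALSE, ordered_result = TRUE)
}

#' Day-weighted mean of a monthly series over a recall window
#'
#' Each calendar day in the (inclusive) recall window carries its month's
#' value; the function returns their mean, i.e. a partial month is weighted by
#' its overlapping days.
#'
#' @param values per-month values.
#' @param months month keys aligned with `values`.
#' @param recall_start,recall_end recall window dates (inclusive).
#' @param day_weighted if `FALSE`, every overlapped month gets equal weight
#'   (the unweighted month-mean variant).
#' @return scalar mean value.
#' @export
recall_mean <- function(values, months, recall_start, recall_end, day_weighted = TRUE) {
  stopifnot(length(values) == length(months))
  w <- vapply(months, function(m) overlap_days(recall_start, recall_end, m), numeric(1))
  if (sum(w) == 0) stop("recall window does not overlap the series", call. = FALSE)
  if (!day_weighted) w <- as.numeric(w > 0)
  keep <- w > 0
  if (anyNA(values[keep])) stop("missing values inside the recall window", call. = FALSE)
  sum(values[keep] * w[keep]) / sum(w[keep])
}

#' Prepare a long-format predictor frame for analysis
#'
#' For each variable and LGA, in order: impute missing values, apply an
#' optional trailing rolling mean, lag by the variable's configured lag, and
#' re-impute the leading lag months (lag-then-impute). The result carries no
#' missing values inside the analysis window.
#'
#' @param frame long data frame: `variable`, `lga_id`, `month`, `value`.
#' @param spec per-variable specification: a data frame with `variable` and
#'   optional `lag` (default 0), `max_lag` (default 6), `smooth_window`
#'   (default 1).
#' @return a frame of the same shape with prepared values.
#' @export
prepare_predictors <- function(frame, spec = NULL) {
  stopifnot(all(c("variable", "lga_id", "month", "value") %in% names(frame)))
  if (is.null(spec)) spec <- data.frame(variable = unique(frame$variable))
  if (is.null(spec$lag)) spec$lag <- 0L
  if (is.null(spec$max_lag)) spec$max_lag <- 6L
  if (is.null(spec$smooth_window)) spec$smooth_window <- 1L
  out <- frame[order(frame$variable, frame$lga_id, frame$month), ]
  for (v in unique(out$variable)) {
    srow <- spec[spec$variable == v, , drop = FALSE]
    if (!nrow(srow)) srow <- data.frame(lag = 0L, max_lag = 6L, smooth_window = 1L)
    for (g in unique(out$lga_id[out$variable == v])) {
      sel <- out$variable == v & out$lga_id == g
      x <- impute_series(out$value[sel], label = paste(v, g))
      x <- rolling_mean(x, srow$smooth_window[1])
      x <- lag_series(x, srow$lag[1], srow$max_lag[1])
      out$value[sel] <- impute_series(x, label = paste(v, g))
    }
  }
  rownames(out) <- NULL
  out
}
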