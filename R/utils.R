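# Month-key helpers. Strata are keyed by "YYYY-MM" strings throughout; these
# convert between keys, Dates and day counts.

#' Month-key utilities
#'
#' Analysis strata are indexed by calendar month, encoded as ISO `"YYYY-MM"`
#' strings. `month_seq()` enumerates the months spanning two keys,
#' `month_start()`/`month_end()` give the first/last calendar day,
#' `days_in_month()` the month length, and `month_shift()` moves a key by a
#' number of months.
#'
#' @param month,from,to month keys, `"YYYY-MM"`.
#' @param k integer number of months to shift by (may be negative).
#' @return `month_seq()` a character vector of keys; `month_start()` and
#'   `month_end()` `Date`s; `days_in_month()` an integer; `month_shift()` a key.
#' @examples
#' month_seq("2016-11", "2017-02")
#' days_in_month("2016-02")
#' @name month-keys
NULL

#' @rdname month-keys
#' @export
month_start <- function(month) {
  stopifnot(grepl("^\\d{4}-\\d{2}$", month))
  as.Date(paste0(month, "-01"))
}

#' @rdname month-keys
#' @export
month_end <- function(month) {
  month_start(month_shift(month, 1L)) - 1L
}

#' @rdname month-keys
#' @export
days_in_month <- function(month) {
  as.integer(month_end(month) - month_start(month)) + 1L
}

#' @rdname month-keys
#' @export
month_shift <- function(month, k) {
  d <- month_start(month)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m")) + as.integer(k)
  y <- y + (m - 1L) %/% 12L
  m <- (m - 1L) %% 12L + 1L
  sprintf("%04d-%02d", y, m)
}

#' @rdname month-keys
#' @export
month_seq <- function(from, to) {
  n <- month_diff(to, from)
  if (n < 0L) stop("'from' is after 'to'", call. = FALSE)
  vapply(0:n, function(k) month_shift(from, k), character(1))
}

#' @rdname month-keys
#' @export
month_key <- function(date) format(as.Date(date), "%Y-%m")

# signed number of months between two keys (a - b)
month_diff <- function(a, b) {
  da <- month_start(a); db <- month_start(b)
  ya <- as.integer(format(da, "%Y")); yb <- as.integer(format(db, "%Y"))
  ma <- as.integer(format(da, "%m")); mb <- as.integer(format(db, "%m"))
  (ya - yb) * 12L + (ma - mb)
}

# inclusive day overlap between a date window and a calendar month
overlap_days <- function(start, end, month) {
  s <- max(as.Date(start), month_start(month))
  e <- min(as.Date(end), month_end(month))
  max(0L, as.integer(e - s) + 1L)
}

# fail with the offending field named, for config validation
check_that <- function(ok, field, what) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: '%s' %s", field, what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Round a death toll for reporting
#'
#' Tolls are printed to the nearest 100 deaths; rates to two decimals. Applied
#' at report time only — internal aggregation always uses unrounded draws.
#'
#' @param x numeric vector of death tolls.
#' @return `x` rounded to the nearest 100.
#' @examples
#' round_toll(908149) # 908100
#' @export
round_toll <- function(x) round(x, -2)
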