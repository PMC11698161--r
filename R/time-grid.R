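#' Discrete time grid for exposure construction
#'
#' Exposure is reasoned about on a discrete grid: calendar months for the
#' grace-period rules and ISO-8601 weeks for the same-week sensitivity rule.
#' Period indices are consecutive integers (months since 0000-01 or ISO weeks
#' since the Monday 1970-01-05), so date-to-period conversion is a bijection
#' and interval arithmetic is plain integer arithmetic.
#'
#' @param resolution `"month"` or `"week"` (ISO-8601 weeks, Monday-based).
#' @param start,end first and last calendar date covered by the data window.
#' @param index_date the cohort index date; must fall inside `[start, end]`.
#' @return an object of class `time_grid` with the span's period bounds and
#'   the index period.
#' @export
time_grid <- function(resolution = c("month", "week"),
                      start = as.Date("2017-01-01"),
                      end = as.Date("2021-12-31"),
                      index_date = as.Date("2021-01-01")) {
  resolution <- match.arg(resolution)
  start <- as.Date(start); end <- as.Date(end); index_date <- as.Date(index_date)
  if (anyNA(c(start, end, index_date))) stop("grid dates must parse", call. = FALSE)
  if (start > end) stop("grid start must not be after end", call. = FALSE)
  if (index_date < start || index_date > end) {
    stop("index_date must lie inside the grid span", call. = FALSE)
  }
  g <- structure(list(resolution = resolution, start = start, end = end,
                      index_date = index_date),
                 class = "time_grid")
  g$period_min <- date_to_period(g, start)
  g$period_max <- date_to_period(g, end)
  g$index_period <- date_to_period(g, index_date)
  g
}

#' Convert dates to period indices and back
#'
#' @param grid a [time_grid()].
#' @param dates a `Date` vector (or parseable `YYYY-MM-DD` strings).
#' @return `date_to_period()`: integer period indices. `period_to_date()`: the
#'   first calendar day of each period (month start, or ISO-week Monday).
#' @export
date_to_period <- function(grid, dates) {
  stopifnot(inherits(grid, "time_grid"))
  dates <- as.Date(dates)
  if (anyNA(dates)) {
    abort_bad_rows("unparseable date(s); expected YYYY-MM-DD", which(is.na(dates)))
  }
  if (grid$resolution == "month") {
    lt <- as.POSIXlt(dates)
    as.integer((lt$year + 1900L) * 12L + lt$mon)
  } else {
    # index of the ISO week, anchored at Monday 1970-01-05 (week 0)
    as.integer(floor((as.integer(dates) - 4L) / 7L))
  }
}

#' @rdname date_to_period
#' @param periods integer period indices.
#' @export
period_to_date <- function(grid, periods) {
  stopifnot(inherits(grid, "time_grid"))
  periods <- as.integer(periods)
  if (grid$resolution == "month") {
    as.Date(sprintf("%04d-%02d-01", periods %/% 12L, periods %% 12L + 1L))
  } else {
    as.Date(periods * 7L + 4L, origin = "1970-01-01")
  }
}

#' Human-readable period labels
#'
#' Months render as `"2021-03"`, ISO weeks as `"2021-W09"`.
#'
#' @inheritParams period_to_date
#' @return character vector of labels.
#' @export
period_label <- function(grid, periods) {
  d <- period_to_date(grid, periods)
  if (grid$resolution == "month") {
    format(d, "%Y-%m")
  } else {
    # ISO year/week of the period's Monday
    paste0(format(d, "%G"), "-W", format(d, "%V"))
  }
}

#' All period indices of a calendar-year study window
#'
#' For month grids, the 12 months of `year`; for week grids, every ISO week
#' overlapping the year (so the week containing 1 January is included even
#' when its Monday falls in December).
#'
#' @param grid a [time_grid()].
#' @param year calendar year (default 2021).
#' @return integer vector of consecutive period indices.
#' @export
study_window <- function(grid, year = 2021L) {
  first <- as.Date(sprintf("%d-01-01", year))
  last <- as.Date(sprintf("%d-12-31", year))
  seq.int(date_to_period(grid, first), date_to_period(grid, last))
}

assert_in_span <- function(grid, periods, what = "period") {
  out <- periods < grid$period_min | periods > grid$period_max
  if (any(out)) {
    abort_bad_rows(sprintf("%s outside the grid span %s..%s", what,
                           period_label(grid, grid$period_min),
                           period_label(grid, grid$period_max)),
                   which(out))
  }
  invisible(periods)
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %s grid %s..%s (periods %d..%d), index %s\n",
              x$resolution, x$start, x$end, x$period_min, x$period_max,
              period_label(x, x$index_period)))
  invisible(x)
}
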