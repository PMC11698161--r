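#' Round half away from zero
#'
#' Rounding convention used for all displayed percentages: ties go up
#' (`round_half_up(7.15, 1) == 7.2`), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a display percentage
#'
#' @param p proportion in `[0, 1]`.
#' @param digits decimal places on the percent scale (default 1, half-up).
#' @return numeric vector on the percent scale, rounded for display.
#' @export
pct <- function(p, digits = 1) round_half_up(100 * p, digits)

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_rows <- function(msg, rows) {
  rows <- utils::head(rows, 10)
  stop(sprintf("%s (rows: %s)", msg, paste(rows, collapse = ", ")), call. = FALSE)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
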