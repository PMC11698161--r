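#' Exposure rules
#'
#' Three rules translate a prescription fill into presumed exposure time:
#' * `month_grace` with `grace = 1` (the main analysis): a fill covers its
#'   calendar month plus one further month, absorbing refill gaps such as
#'   stockpiling;
#' * `month_grace` with `grace = 2` (sensitivity): two further months;
#' * `same_week` (sensitivity): a fill covers exactly its ISO week, with no
#'   grace period.
#'
#' @param kind `"month_grace"` or `"same_week"`.
#' @param grace non-negative integer number of grace months; forced to 0 for
#'   `same_week`.
#' @return an object of class `exposure_rule`.
#' @export
exposure_rule <- function(kind = c("month_grace", "same_week"), grace = 1L) {
  kind <- match.arg(kind)
  grace <- as.integer(grace)
  if (is.na(grace) || grace < 0L) stop("`grace` must be an integer >= 0", call. = FALSE)
  if (kind == "same_week") grace <- 0L
  structure(list(kind = kind, grace = grace,
                 resolution = if (kind == "same_week") "week" else "month"),
            class = "exposure_rule")
}

rule_id <- function(rule) {
  if (rule$kind == "same_week") "same_week" else sprintf("month_grace_%d", rule$grace)
}

#' @export
print.exposure_rule <- function(x, ...) {
  cat("<exposure_rule>", rule_id(x), "\n"); invisible(x)
}

#' Default grid for an exposure rule
#'
#' @param rule an [exposure_rule()].
#' @inheritParams time_grid
#' @return a [time_grid()] at the rule's resolution.
#' @export
grid_for_rule <- function(rule, start = as.Date("2017-01-01"),
                          end = as.Date("2021-12-31"),
                          index_date = as.Date("2021-01-01")) {
  time_grid(rule$resolution, start = start, end = end, index_date = index_date)
}

#' Build per-agent exposure intervals from prescription fills
#'
#' Non-CNS fills are dropped via the classification; each remaining fill of an
#' agent contributes coverage of periods `[m, m + grace]` (clipped at the grid
#' end), and per (patient, agent) overlapping or adjacent coverage is merged
#' into maximal disjoint intervals. Quantity columns (pills, boxes, mg) do not
#' affect duration: the source registry records no days of supply.
#'
#' @param fills data frame with columns `patient_id`, `fill_date`, `atc_code`
#'   (additional columns are ignored).
#' @param classification an [atc_classification()].
#' @param rule an [exposure_rule()].
#' @param grid a [time_grid()] whose resolution matches the rule; defaults to
#'   [grid_for_rule()] of `rule`.
#' @return tibble of intervals with columns `patient_id`, `atc_code`,
#'   `drug_class`, `start`, `end` (inclusive period indices), `rule`; sorted by
#'   (patient, agent, start). The rule and grid travel along as attributes.
#' @export
build_exposures <- function(fills, classification = default_classification(),
                            rule = exposure_rule("month_grace", 1L),
                            grid = grid_for_rule(rule)) {
  stopifnot(inherits(rule, "exposure_rule"), inherits(grid, "time_grid"))
  if (grid$resolution != rule$resolution) {
    stop(sprintf("rule %s needs a %s-resolution grid", rule_id(rule),
                 rule$resolution), call. = FALSE)
  }
  fills <- tibble::as_tibble(fills)
  need <- c("patient_id", "fill_date", "atc_code")
  if (!all(need %in% names(fills))) {
    stop("fills must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(patient_id = fills$patient_id[0],
                          atc_code = character(), drug_class = character(),
                          start = integer(), end = integer(),
                          rule = character())
  if (nrow(fills) == 0L) {
    return(structure(empty, exposure_rule = rule, time_grid = grid))
  }
  dates <- if (inherits(fills$fill_date, "Date")) fills$fill_date else
    as.Date(as.character(fills$fill_date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    abort_bad_rows("unparseable fill_date; expected YYYY-MM-DD", which(is.na(dates)))
  }
  if (any(dates < grid$start | dates > grid$end)) {
    abort_bad_rows("fill dated outside the grid span",
                   which(dates < grid$start | dates > grid$end))
  }
  cls <- classify_atc(fills$atc_code, classification)
  keep <- !is.na(cls)
  if (!any(keep)) return(structure(empty, exposure_rule = rule, time_grid = grid))

  cov <- tibble::tibble(patient_id = fills$patient_id[keep],
                        atc_code = toupper(fills$atc_code[keep]),
                        drug_class = cls[keep],
                        period = date_to_period(grid, dates[keep]))
  if (rule$grace > 0L) {
    cov <- tidyr::uncount(cov, weights = rule$grace + 1L, .id = "offset")
    cov$period <- pmin(cov$period + cov$offset - 1L, grid$period_max)
    cov$offset <- NULL
  }
  out <- cov |>
    dplyr::distinct(.data$patient_id, .data$atc_code, .data$drug_class,
                    .data$period) |>
    dplyr::arrange(.data$patient_id, .data$atc_code, .data$period) |>
    dplyr::group_by(.data$patient_id, .data$atc_code, .data$drug_class) |>
    dplyr::mutate(gap = cumsum(c(0L, diff(.data$period) > 1L))) |>
    dplyr::group_by(.data$gap, .add = TRUE) |>
    dplyr::summarise(start = min(.data$period), end = max(.data$period),
                     .groups = "drop") |>
    dplyr::select(-"gap") |>
    dplyr::mutate(rule = rule_id(rule)) |>
    dplyr::arrange(.data$patient_id, .data$atc_code, .data$start)
  structure(out, exposure_rule = rule, time_grid = grid)
}

#' Agents concurrently covered at one period
#'
#' @param intervals output of [build_exposures()].
#' @param patient_id single patient identifier.
#' @param period single period index inside the grid span.
#' @return tibble with one row per covered agent: `atc_code`, `drug_class`
#'   (set semantics: an agent appears once however many fills support it).
#' @export
concurrent_agents <- function(intervals, patient_id, period) {
  grid <- attr(intervals, "time_grid")
  if (!is.null(grid)) assert_in_span(grid, period)
  intervals |>
    dplyr::filter(.data$patient_id == !!patient_id,
                  .data$start <= !!period, .data$end >= !!period) |>
    dplyr::distinct(.data$atc_code, .data$drug_class)
}
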