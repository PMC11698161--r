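#' Enumerate CNS-active polypharmacy events
#'
#' A polypharmacy event is one patient-period (month, or ISO week under the
#' same-week rule) in the study window during which the patient is concurrently
#' exposed to at least `threshold` distinct CNS-active agents (distinct by full
#' 7-character ATC code — three distinct benzodiazepines qualify). Multiple
#' events per patient are emitted; the event's agent set is the full concurrent
#' set for that period, with no restriction on class composition.
#'
#' @param intervals output of [build_exposures()] for a single rule.
#' @param window integer vector of period indices to scan; defaults to the 2021
#'   calendar-year window of the intervals' grid.
#' @param threshold minimum number of distinct concurrent agents (default 3).
#' @return tibble with one row per event: `patient_id`, `period`,
#'   `period_label`, `rule`, `n_agents`, `agents` (semicolon-joined sorted ATC
#'   codes), `classes` (semicolon-joined sorted class multiset).
#' @export
detect_events <- function(intervals, window = NULL, threshold = 3L) {
  grid <- attr(intervals, "time_grid")
  rule <- attr(intervals, "exposure_rule")
  if (is.null(grid) || is.null(rule)) {
    stop("`intervals` must come from build_exposures()", call. = FALSE)
  }
  if (length(unique(intervals$rule)) > 1L) {
    stop("intervals mix exposure rules; detect events one rule at a time",
         call. = FALSE)
  }
  threshold <- as.integer(threshold)
  if (is.null(window)) window <- study_window(grid, 2021L)
  assert_in_span(grid, window, "study window")

  empty <- tibble::tibble(patient_id = intervals$patient_id[0],
                          period = integer(), period_label = character(),
                          rule = character(), n_agents = integer(),
                          agents = character(), classes = character())
  if (nrow(intervals) == 0L) {
    return(structure(empty, time_grid = grid, exposure_rule = rule,
                     threshold = threshold))
  }

  # clip intervals to the window, then expand to (patient, agent, period)
  clipped <- intervals |>
    dplyr::mutate(start = pmax(.data$start, min(window)),
                  end = pmin(.data$end, max(window))) |>
    dplyr::filter(.data$start <= .data$end)
  if (nrow(clipped) == 0L) {
    return(structure(empty, time_grid = grid, exposure_rule = rule,
                     threshold = threshold))
  }
  out <- clipped |>
    dplyr::mutate(len = .data$end - .data$start + 1L) |>
    tidyr::uncount(weights = .data$len, .id = "off") |>
    dplyr::mutate(period = .data$start + .data$off - 1L) |>
    dplyr::distinct(.data$patient_id, .data$period, .data$atc_code,
                    .data$drug_class) |>
    dplyr::group_by(.data$patient_id, .data$period) |>
    dplyr::filter(dplyr::n() >= threshold) |>
    dplyr::arrange(.data$atc_code, .by_group = TRUE) |>
    dplyr::summarise(n_agents = dplyr::n(),
                     agents = paste(.data$atc_code, collapse = ";"),
                     classes = paste(sort(.data$drug_class), collapse = ";"),
                     .groups = "drop") |>
    dplyr::mutate(period_label = period_label(grid, .data$period),
                  rule = rule_id(rule)) |>
    dplyr::select("patient_id", "period", "period_label", "rule",
                  "n_agents", "agents", "classes") |>
    dplyr::arrange(.data$patient_id, .data$period)
  structure(out, time_grid = grid, exposure_rule = rule, threshold = threshold)
}

#' Tally events, medications, classes and class combinations
#'
#' @param events output of [detect_events()].
#' @return a list of class `event_summary`:
#' \describe{
#'   \item{n_events}{number of patient-period events}
#'   \item{n_patients_with_event}{distinct patients with at least one event}
#'   \item{n_medication_records}{sum of event sizes (one record per agent per
#'     event)}
#'   \item{first_event_period_by_patient}{tibble `patient_id`, `first_period`}
#'   \item{class_frequency}{tibble `drug_class`, `n`, `pct_of_medications`}
#'   \item{combination_frequency}{tibble `combination` (canonical sorted class
#'     multiset), `n`, `pct_of_events`}
#'   \item{agent_frequency}{tibble `atc_code`, `n`, `pct_of_medications`}
#' }
#' Conservation laws: combination counts sum to `n_events`; class and agent
#' counts each sum to `n_medication_records`.
#' @export
summarize_events <- function(events) {
  events <- tibble::as_tibble(events)
  n_events <- nrow(events)
  long <- if (n_events) {
    events |>
      dplyr::mutate(atc_code = strsplit(.data$agents, ";", fixed = TRUE),
                    drug_class = strsplit(.data$classes, ";", fixed = TRUE)) |>
      tidyr::unnest(c("atc_code", "drug_class"))
  } else {
    tibble::tibble(atc_code = character(), drug_class = character())
  }
  n_meds <- nrow(long)
  cf <- long |> dplyr::count(.data$drug_class, sort = TRUE, name = "n") |>
    dplyr::mutate(pct_of_medications = pct(.data$n / max(n_meds, 1L)))
  af <- long |> dplyr::count(.data$atc_code, sort = TRUE, name = "n") |>
    dplyr::mutate(pct_of_medications = pct(.data$n / max(n_meds, 1L)))
  comb <- events |>
    dplyr::count(combination = .data$classes, sort = TRUE, name = "n") |>
    dplyr::mutate(pct_of_events = pct(.data$n / max(n_events, 1L)))
  first <- if (n_events) {
    events |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_period = min(.data$period), .groups = "drop")
  } else {
    tibble::tibble(patient_id = events$patient_id[0], first_period = integer())
  }
  structure(list(
    n_events = n_events,
    n_patients_with_event = nrow(first),
    n_medication_records = n_meds,
    first_event_period_by_patient = first,
    class_frequency = cf,
    combination_frequency = comb,
    agent_frequency = af
  ), class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("<event_summary> %d events, %d patients, %d medication records\n",
              x$n_events, x$n_patients_with_event, x$n_medication_records))
  invisible(x)
}

#' Time from index to a patient's first polypharmacy event
#'
#' Patients already in polypharmacy at the index period score 0. The median
#' and interquartile range use `stats::quantile()` type 7 (linear
#' interpolation), computed over patients with at least one event.
#'
#' @param events output of [detect_events()].
#' @param index_period the index period; defaults to the grid's index period.
#' @return list with `by_patient` (tibble `patient_id`, `months` — periods
#'   from index in grid units), `median`, `iqr` (length-2 vector, 25th and
#'   75th percentiles).
#' @export
time_to_first_event <- function(events, index_period = NULL) {
  grid <- attr(events, "time_grid")
  if (is.null(index_period)) {
    if (is.null(grid)) stop("supply `index_period` or events from detect_events()",
                            call. = FALSE)
    index_period <- grid$index_period
  }
  by_patient <- events |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(months = min(.data$period) - index_period, .groups = "drop")
  if (nrow(by_patient) == 0L) {
    return(list(by_patient = by_patient, median = NA_real_,
                iqr = c(NA_real_, NA_real_)))
  }
  q <- stats::quantile(by_patient$months, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  list(by_patient = by_patient, median = q[2], iqr = q[c(1, 3)])
}
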