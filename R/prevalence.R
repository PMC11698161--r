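#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval obtained by inverting the binomial tail probabilities,
#' computed through the equivalent Beta-quantile endpoints:
#' `low = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `high = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). The method is
#' conservative: coverage is at least the nominal level.
#'
#' @param x number of successes (vectorised).
#' @param n number of trials.
#' @param alpha error level (default 0.05 for a 95% interval).
#' @return tibble with columns `low`, `high` (proportions).
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (any(!is.finite(x)) || any(!is.finite(n)) || any(x < 0) || any(x > n) ||
      any(n < 1)) {
    stop("need 0 <= x <= n and n >= 1", call. = FALSE)
  }
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  low <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  high <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(low = low, high = high)
}

prevalence_row <- function(numerator, denominator, alpha, stratum) {
  ci <- clopper_pearson(numerator, denominator, alpha)
  tibble::tibble(stratum = stratum, numerator = numerator,
                 denominator = denominator,
                 point = numerator / denominator,
                 ci_low = ci$low, ci_high = ci$high, alpha = alpha)
}

#' Period prevalence of CNS-active polypharmacy
#'
#' Numerator: distinct cohort members with at least one event during the study
#' window (the window includes the index period, so prevalent users at index
#' are counted). Denominator: the full index-date cohort, including patients
#' later censored by death or disaffiliation.
#'
#' @param events output of [detect_events()].
#' @param cohort patient baseline table with a `patient_id` column.
#' @param alpha error level for the Clopper-Pearson interval.
#' @param stratum label for the estimate row (default `"overall"`).
#' @return one-row tibble: `stratum`, `numerator`, `denominator`, `point`,
#'   `ci_low`, `ci_high`, `alpha`.
#' @export
period_prevalence <- function(events, cohort, alpha = 0.05,
                              stratum = "overall") {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  ids <- unique(events$patient_id)
  extra <- setdiff(ids, cohort$patient_id)
  if (length(extra)) {
    stop("events reference patients absent from the cohort: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  prevalence_row(length(ids), nrow(cohort), alpha, stratum)
}

#' Split patients into prevalent and incident polypharmacy users
#'
#' Prevalent users are in polypharmacy at the index period; incident users
#' have their first event strictly after it. The two sets are disjoint and
#' together cover every patient with an event.
#'
#' @param events output of [detect_events()] on a window that includes the
#'   index period.
#' @param index_period index period; defaults to the grid's.
#' @return list with character/whatever-id vectors `prevalent` and `incident`.
#' @export
split_prevalent_incident <- function(events, index_period = NULL) {
  grid <- attr(events, "time_grid")
  if (is.null(index_period)) {
    if (is.null(grid)) stop("supply `index_period`", call. = FALSE)
    index_period <- grid$index_period
  }
  first <- events |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_period = min(.data$period), .groups = "drop")
  list(prevalent = first$patient_id[first$first_period <= index_period],
       incident = first$patient_id[first$first_period > index_period])
}

#' Subgroup period prevalence
#'
#' One estimate per level of a stratifying column; strata partition the
#' cohort, so subgroup numerators and denominators are additive to the
#' overall ones. Empty strata are omitted with a warning.
#'
#' @param events output of [detect_events()].
#' @param cohort baseline table with `patient_id` and the stratifier column.
#' @param stratifier name of a column of `cohort` (e.g. `"dementia"` or
#'   `"age_band"`); must be non-missing for every patient.
#' @param alpha error level.
#' @return tibble with one [period_prevalence()] row per stratum.
#' @export
subgroup_prevalence <- function(events, cohort, stratifier, alpha = 0.05) {
  cohort <- tibble::as_tibble(cohort)
  if (!stratifier %in% names(cohort)) {
    stop(sprintf("cohort has no column `%s`", stratifier), call. = FALSE)
  }
  strat <- cohort[[stratifier]]
  if (anyNA(strat)) stop("stratifier must be a total function on the cohort",
                         call. = FALSE)
  levs <- if (is.factor(strat)) levels(strat) else sort(unique(strat))
  ev_ids <- unique(events$patient_id)
  out <- lapply(levs, function(l) {
    sub <- cohort$patient_id[strat == l]
    if (length(sub) == 0L) {
      warning(sprintf("stratum `%s=%s` has no members; omitted", stratifier, l))
      return(NULL)
    }
    prevalence_row(sum(ev_ids %in% sub), length(sub), alpha,
                   sprintf("%s=%s", stratifier, l))
  })
  dplyr::bind_rows(out)
}

#' Assign the study's age bands
#'
#' Bands 60-69, 70-79 and 80+ (80 years and older, inclusive), covering the
#' cohort exactly.
#'
#' @param age_years numeric vector of ages at index (all `>= 60`).
#' @return factor with levels `"60-69"`, `"70-79"`, `"80+"`.
#' @export
age_band <- function(age_years) {
  if (any(age_years < 60, na.rm = TRUE)) {
    stop("cohort members must be aged 60 or older at index", call. = FALSE)
  }
  cut(age_years, breaks = c(60, 70, 80, Inf), right = FALSE,
      labels = c("60-69", "70-79", "80+"))
}
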