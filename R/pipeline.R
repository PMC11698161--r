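#' Validate pipeline input files
#'
#' Checks the patient baseline and fill CSVs before analysis: required
#' columns, date parsing, ATC syntax, duplicate fill rows (reported, kept)
#' and fills referencing patients absent from the baseline table (error).
#'
#' @param patients_path,fills_path CSV paths.
#' @return a list validation report: `ok`, `errors` (character), `warnings`
#'   (character), `n_patients`, `n_fills`; machine-readable and printable.
#' @export
validate_inputs <- function(patients_path, fills_path) {
  errors <- character(0); warns <- character(0)
  patients <- readr::read_csv(patients_path, show_col_types = FALSE,
                              progress = FALSE)
  fills <- readr::read_csv(fills_path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(fill_date = "c",
                                                   .default = readr::col_guess()))
  need_p <- c("patient_id", "age_years")
  need_f <- c("patient_id", "fill_date", "atc_code")
  mp <- setdiff(need_p, names(patients))
  mf <- setdiff(need_f, names(fills))
  if (length(mp)) errors <- c(errors, paste("patients.csv lacks columns:",
                                            paste(mp, collapse = ", ")))
  if (length(mf)) errors <- c(errors, paste("fills.csv lacks columns:",
                                            paste(mf, collapse = ", ")))
  if (!length(mf)) {
    d <- as.Date(fills$fill_date, format = "%Y-%m-%d")
    if (anyNA(d)) {
      errors <- c(errors, sprintf("unparseable fill_date at rows: %s",
                                  paste(utils::head(which(is.na(d)), 10),
                                        collapse = ", ")))
    }
    bad_atc <- !grepl(ATC_FULL_RE, toupper(trimws(fills$atc_code)))
    if (any(bad_atc)) {
      errors <- c(errors, sprintf("malformed ATC code at rows: %s",
                                  paste(utils::head(which(bad_atc), 10),
                                        collapse = ", ")))
    }
    ndup <- sum(duplicated(fills))
    if (ndup > 0) {
      warns <- c(warns, sprintf("%d duplicate fill rows (kept)", ndup))
    }
    if (!length(mp)) {
      orphan <- !fills$patient_id %in% patients$patient_id
      if (any(orphan)) {
        errors <- c(errors,
                    sprintf("fills reference patients absent from baseline at rows: %s",
                            paste(utils::head(which(orphan), 10), collapse = ", ")))
      }
    }
  }
  if (!length(mp) && anyDuplicated(patients$patient_id)) {
    errors <- c(errors, "duplicate patient_id in baseline table")
  }
  list(ok = length(errors) == 0L, errors = errors, warnings = warns,
       n_patients = nrow(patients), n_fills = nrow(fills))
}

#' Pipeline run configuration
#'
#' @param patients_path,fills_path input CSVs.
#' @param out_dir output directory for tables and the manifest.
#' @param rules character subset of `c("month_grace_1", "same_week",
#'   "month_grace_2")`; the first is the main analysis.
#' @param classification an [atc_classification()].
#' @param year calendar year of the study window.
#' @param alpha error level for all intervals.
#' @param subgroups cohort columns to stratify prevalence by (under the main
#'   rule); defaults to dementia status and age band.
#' @param covariates model covariates for the association tables; `NULL`
#'   selects those of [default_covariates()] present in the baseline table.
#' @return list of class `run_config`.
#' @export
run_config <- function(patients_path, fills_path, out_dir,
                       rules = c("month_grace_1", "same_week", "month_grace_2"),
                       classification = default_classification(),
                       year = 2021L, alpha = 0.05,
                       subgroups = c("dementia", "age_band"),
                       covariates = NULL) {
  known <- c("month_grace_1", "same_week", "month_grace_2")
  if (length(rules) == 0L || !all(rules %in% known)) {
    stop("rules must be a non-empty subset of: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  structure(list(patients_path = patients_path, fills_path = fills_path,
                 out_dir = out_dir, rules = rules,
                 classification = classification, year = as.integer(year),
                 alpha = alpha, subgroups = subgroups,
                 covariates = covariates),
            class = "run_config")
}

# keep only covariates the strict fitters can estimate: binary flags need all
# four outcome-by-flag cells occupied, and every covariate needs variance
screen_covariates <- function(data, outcome, covariates) {
  y <- data[[outcome]]
  ok <- vapply(covariates, function(v) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) return(FALSE)
    if (all(x %in% c(0, 1))) {
      all(table(factor(x, c(0, 1)), factor(y, c(0, 1))) > 0)
    } else TRUE
  }, logical(1))
  if (!all(ok)) {
    warning("excluding covariate(s) with empty cells or no variance: ",
            paste(covariates[!ok], collapse = ", "), call. = FALSE)
  }
  covariates[ok]
}

parse_rule <- function(id) {
  switch(id,
         month_grace_1 = exposure_rule("month_grace", 1L),
         month_grace_2 = exposure_rule("month_grace", 2L),
         same_week = exposure_rule("same_week"),
         stop("unknown rule id: ", id, call. = FALSE))
}

#' Run the full polypharmacy analysis pipeline
#'
#' Validates inputs, builds exposures and events under each requested rule,
#' and writes five tables plus a JSON manifest to the output directory:
#' `prevalence.csv` (all rules, prevalent/incident split and subgroups under
#' the main rule), `association.csv` (bivariate and multivariable odds
#' ratios), `combinations.csv` (class-combination frequencies per event),
#' `classes.csv` and `agents.csv` (medication-level frequencies), and
#' `manifest.json` (row counts, package version, config echo). Deterministic:
#' identical inputs give byte-identical tables. On validation failure no
#' partial output is left behind.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rep <- validate_inputs(config$patients_path, config$fills_path)
  if (!rep$ok) {
    stop("input validation failed:\n  ", paste(rep$errors, collapse = "\n  "),
         call. = FALSE)
  }
  for (w in rep$warnings) warning(w, call. = FALSE)
  cohort <- readr::read_csv(config$patients_path, show_col_types = FALSE,
                            progress = FALSE)
  fills <- readr::read_csv(config$fills_path, show_col_types = FALSE,
                           progress = FALSE)
  if (!"age_band" %in% names(cohort)) {
    cohort$age_band <- age_band(cohort$age_years)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  main_rule <- config$rules[[1]]
  prev_rows <- list(); events_by_rule <- list()
  for (rid in config$rules) {
    rule <- parse_rule(rid)
    grid <- grid_for_rule(rule,
                          index_date = as.Date(sprintf("%d-01-01", config$year)))
    iv <- build_exposures(fills, config$classification, rule, grid)
    ev <- detect_events(iv, window = study_window(grid, config$year))
    events_by_rule[[rid]] <- ev
    prev_rows[[rid]] <- period_prevalence(ev, cohort, config$alpha,
                                          stratum = "overall") |>
      dplyr::mutate(rule = rid, .before = 1)
  }

  ev_main <- events_by_rule[[main_rule]]
  split <- split_prevalent_incident(ev_main)
  extra <- dplyr::bind_rows(
    prevalence_row(length(split$prevalent), nrow(cohort), config$alpha,
                   "prevalent_users"),
    prevalence_row(length(split$incident), nrow(cohort), config$alpha,
                   "incident_users")) |>
    dplyr::mutate(rule = main_rule, .before = 1)
  sub_rows <- lapply(intersect(config$subgroups, names(cohort)), function(s) {
    subgroup_prevalence(ev_main, cohort, s, config$alpha) |>
      dplyr::mutate(rule = main_rule, .before = 1)
  })
  prevalence <- dplyr::bind_rows(c(prev_rows, list(extra), sub_rows)) |>
    dplyr::mutate(percent = pct(.data$point),
                  ci_low_pct = pct(.data$ci_low),
                  ci_high_pct = pct(.data$ci_high))

  summ <- summarize_events(ev_main)
  outcome_ids <- unique(ev_main$patient_id)
  model_data <- cohort |>
    dplyr::mutate(polypharmacy = as.integer(.data$patient_id %in% outcome_ids))
  covs <- config$covariates %||%
    intersect(default_covariates(), names(model_data))
  covs <- screen_covariates(model_data, "polypharmacy", covs)
  assoc <- association_table(model_data, "polypharmacy", covs, config$alpha)

  paths <- file.path(config$out_dir,
                     c("prevalence.csv", "association.csv", "combinations.csv",
                       "classes.csv", "agents.csv"))
  names(paths) <- c("prevalence", "association", "combinations", "classes",
                    "agents")
  readr::write_csv(prevalence, paths["prevalence"], progress = FALSE)
  readr::write_csv(assoc, paths["association"], progress = FALSE)
  readr::write_csv(summ$combination_frequency, paths["combinations"],
                   progress = FALSE)
  readr::write_csv(summ$class_frequency, paths["classes"], progress = FALSE)
  readr::write_csv(summ$agent_frequency, paths["agents"], progress = FALSE)

  ttfe <- time_to_first_event(ev_main)
  manifest <- list(
    package_version = as.character(utils::packageVersion("polypharm")),
    n_patients = nrow(cohort), n_fills = nrow(fills),
    rules = config$rules, main_rule = main_rule, year = config$year,
    alpha = config$alpha,
    n_events = summ$n_events,
    n_patients_with_event = summ$n_patients_with_event,
    n_medication_records = summ$n_medication_records,
    n_prevalent_users = length(split$prevalent),
    n_incident_users = length(split$incident),
    median_months_to_first_event = ttfe$median,
    iqr_months_to_first_event = ttfe$iqr,
    tables = as.list(basename(paths)),
    input_warnings = rep$warnings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
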