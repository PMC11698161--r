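#' Covariates for the exploratory polypharmacy model
#'
#' Coding conventions: `age_band` enters as indicator variables with 60-69 as
#' the reference level; `n_admissions` enters as a discrete count (the OR
#' compares groups differing by one prior-year admission); every other
#' covariate is a 0/1 flag.
#'
#' @return character vector of covariate column names, for use in the
#'   `covariates` argument of [fit_multivariable()].
#' @export
default_covariates <- function() {
  c("age_band", "female", "anxiety", "depressive", "sleep_disorder",
    "dementia", "bipolar", "schizophrenia", "epilepsy", "hypertension",
    "diabetes", "tobacco", "n_admissions")
}

prepare_model_data <- function(data, outcome, covariates) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(c(outcome, covariates), names(data))
  if (length(miss)) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if ("age_band" %in% covariates) {
    data$age_band <- factor(data$age_band, levels = c("60-69", "70-79", "80+"))
  }
  # zero-variance covariates cannot be estimated; drop with a warning
  keep <- vapply(covariates, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))
  if (!all(keep)) {
    warning("dropping zero-variance covariate(s): ",
            paste(covariates[!keep], collapse = ", "), call. = FALSE)
  }
  list(data = data, covariates = covariates[keep])
}

wald_or <- function(fit, kind, alpha = 0.05) {
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(
    variable = rownames(co),
    odds_ratio = unname(exp(co[, "Estimate"])),
    ci_low = unname(exp(co[, "Estimate"] - z * co[, "Std. Error"])),
    ci_high = unname(exp(co[, "Estimate"] + z * co[, "Std. Error"])),
    p_value = unname(co[, "Pr(>|z|)"]),
    kind = kind
  )
}

check_convergence <- function(fit, covariates) {
  # |beta| ~ 15 on the logit scale signals (quasi-)separation
  co <- stats::coef(fit)
  big <- names(co)[abs(co) > 15 & names(co) != "(Intercept)"]
  if (!fit$converged || length(big)) {
    stop("logistic fit did not converge (possible separation in: ",
         paste(if (length(big)) big else covariates, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(fit)
}

#' Multivariable logistic model for factors associated with polypharmacy
#'
#' Maximum-likelihood logistic regression of a patient-level polypharmacy
#' indicator on baseline covariates; odds ratios are exponentiated
#' coefficients with Wald confidence intervals
#' `exp(beta +/- z[1-alpha/2] * SE)`. Because the outcome mixes prevalent and
#' incident users, estimates are exploratory associations, not causal effects.
#'
#' @param data patient-level table (complete cases are required).
#' @param outcome name of the binary outcome column (default
#'   `"polypharmacy"`).
#' @param covariates character vector of covariate columns; see
#'   [default_covariates()] for the coding conventions.
#' @param alpha error level for the Wald intervals.
#' @return tibble of [wald_or()] rows: `variable`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `kind = "multivariable"`.
#' @export
fit_multivariable <- function(data, outcome = "polypharmacy",
                              covariates = default_covariates(),
                              alpha = 0.05) {
  prep <- prepare_model_data(data, outcome, covariates)
  if (length(prep$covariates) == 0L) stop("no estimable covariates", call. = FALSE)
  f <- stats::reformulate(prep$covariates, response = outcome)
  fit <- stats::glm(f, family = stats::binomial(), data = prep$data,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  check_convergence(fit, prep$covariates)
  wald_or(fit, "multivariable", alpha)
}

#' Bivariate (single-covariate) logistic associations
#'
#' One univariate logistic fit per covariate; for a binary covariate this
#' equals the 2x2 cross-product odds ratio. A zero cell in the implied 2x2
#' table is an error (no silent continuity correction).
#'
#' @inheritParams fit_multivariable
#' @param covariate a single covariate name, or a vector to fit one at a time.
#' @return tibble of OR rows with `kind = "bivariate"`.
#' @export
fit_bivariate <- function(data, covariate, outcome = "polypharmacy",
                          alpha = 0.05) {
  out <- lapply(covariate, function(v) {
    prep <- prepare_model_data(data, outcome, v)
    if (length(prep$covariates) == 0L) {
      stop(sprintf("covariate `%s` has zero variance", v), call. = FALSE)
    }
    x <- prep$data[[v]]
    if (all(x %in% c(0, 1))) {
      tab <- table(factor(x, c(0, 1)), factor(prep$data[[outcome]], c(0, 1)))
      if (any(tab == 0)) {
        stop(sprintf(
          "zero cell in the 2x2 table for `%s`; consider pooling levels or a continuity adjustment",
          v), call. = FALSE)
      }
    }
    fit <- stats::glm(stats::reformulate(v, response = outcome),
                      family = stats::binomial(), data = prep$data,
                      control = stats::glm.control(epsilon = 1e-10, maxit = 50))
    check_convergence(fit, v)
    wald_or(fit, "bivariate", alpha)
  })
  dplyr::bind_rows(out)
}

#' Side-by-side bivariate and multivariable odds-ratio table
#'
#' @inheritParams fit_multivariable
#' @return tibble with one row per covariate term and columns for both model
#'   kinds (`or_bivariate`, `ci_low_bivariate`, ... , `or_multivariable`, ...).
#' @export
association_table <- function(data, outcome = "polypharmacy",
                              covariates = default_covariates(),
                              alpha = 0.05) {
  multi <- fit_multivariable(data, outcome, covariates, alpha)
  bi <- fit_bivariate(data, covariates, outcome, alpha)
  dplyr::full_join(
    dplyr::rename_with(bi, ~ paste0(.x, "_bivariate"), -"variable"),
    dplyr::rename_with(multi, ~ paste0(.x, "_multivariable"), -"variable"),
    by = "variable"
  ) |>
    dplyr::select(-dplyr::starts_with("kind"))
}
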