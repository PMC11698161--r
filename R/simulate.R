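#' Configuration for the synthetic claims generator
#'
#' The generator emulates an HMO pharmacy registry for adults aged 60+ with a
#' 1 January 2021 index date and a 2017-2021 data window. A patient-level
#' latent logistic propensity (intercept plus covariate log-odds) draws a
#' ground-truth polypharmacy indicator; fills are then constructed so that
#' every true case has at least three distinct CNS-active agents filled
#' together in one in-window month (hence is detected under the 1-month-grace
#' rule), while controls never exceed two concurrent agents under that rule.
#' A small fraction of controls are "switchers" (two agents stopped two months
#' before a third starts) whose single triple-concurrency month is visible
#' only under the 2-month-grace rule. Pharmacy visits are batched onto a
#' single day of the month with probability `batch_prob`, which governs how
#' many events the no-grace same-week rule can see.
#'
#' The default intercept (-3.8558) is calibrated so the marginal event
#' probability under the default covariate mix is 0.071.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; fully determines both cohort and fills
#'   (Mersenne-Twister).
#' @param age_band_probs probabilities of bands 60-69 / 70-79 / 80+ (sum 1).
#' @param female_prob probability of female gender.
#' @param diagnosis_prevalences named probabilities for the baseline flags.
#' @param depressive_given_anxiety conditional probability inducing a mild
#'   positive anxiety-depression correlation (marginals are preserved).
#' @param true_log_odds named log odds ratios of the latent propensity; names
#'   follow the model's term names (`age_band70-79`, `female`, ...).
#' @param intercept latent-model intercept.
#' @param admission_mean Poisson mean of prior-year hospital admissions.
#' @param death_rate,disaffiliation_rate annual censoring risks during 2021.
#' @param prevalent_user_frac fraction of true cases already in polypharmacy
#'   at the index date.
#' @param extra_agent_mean Poisson mean of agents beyond the third.
#' @param episode_duration_mean Poisson mean of episode months beyond the
#'   first.
#' @param incident_start_decay geometric-decay weight for the first-event
#'   month of incident cases.
#' @param refill_prob monthly probability a current user refills an agent.
#' @param stockpile_prob probability a due refill was bought ahead (double
#'   boxes the month before, no fill that month).
#' @param batch_prob probability all of a patient's fills in a month happen on
#'   one pharmacy visit day.
#' @param background_user_prob probability a control uses one or two CNS
#'   agents.
#' @param switcher_prob probability a control is a staggered medication
#'   switcher.
#' @param noise_fill_mean Poisson mean of non-CNS fills per patient.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000L,
                             seed = 20210101L,
                             age_band_probs = c("60-69" = 0.40,
                                                "70-79" = 0.38,
                                                "80+" = 0.22),
                             female_prob = 0.62,
                             diagnosis_prevalences = c(
                               anxiety = 0.21, depressive = 0.14,
                               sleep_disorder = 0.11, dementia = 0.05,
                               bipolar = 0.012, schizophrenia = 0.006,
                               epilepsy = 0.02, hypertension = 0.55,
                               diabetes = 0.17, tobacco = 0.20),
                             depressive_given_anxiety = 0.25,
                             true_log_odds = c(
                               "age_band70-79" = log(1.1),
                               "age_band80+" = log(2.3),
                               female = log(1.3), anxiety = log(2.0),
                               depressive = log(3.5), sleep_disorder = log(1.8),
                               dementia = log(4.0), bipolar = log(7.2),
                               schizophrenia = log(7.9), epilepsy = log(2.5),
                               hypertension = 0, diabetes = 0,
                               tobacco = log(1.2), n_admissions = log(1.3)),
                             intercept = -3.8558,
                             admission_mean = 0.15,
                             death_rate = 0.037,
                             disaffiliation_rate = 0.007,
                             prevalent_user_frac = 0.267,
                             extra_agent_mean = 0.3,
                             episode_duration_mean = 5,
                             incident_start_decay = 0.92,
                             refill_prob = 0.85,
                             stockpile_prob = 0.12,
                             batch_prob = 0.4,
                             background_user_prob = 0.25,
                             switcher_prob = 0.007,
                             noise_fill_mean = 2) {
  cfg <- mget(names(formals()))
  stopifnot(n_patients >= 0, length(age_band_probs) == 3)
  if (abs(sum(age_band_probs) - 1) > 1e-8) {
    stop("age_band_probs must sum to 1", call. = FALSE)
  }
  for (nm in c("female_prob", "depressive_given_anxiety",
               "prevalent_user_frac", "refill_prob", "stockpile_prob",
               "batch_prob", "background_user_prob", "switcher_prob")) {
    assert_prob(cfg[[nm]], nm)
  }
  assert_prob(diagnosis_prevalences, "diagnosis_prevalences")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n=%d, seed=%d, marginal target prevalence via intercept %.3f\n",
              x$n_patients, x$seed, x$intercept))
  invisible(x)
}

# Agent pools per class; weights echo the most dispensed study drugs
# (clonazepam, quetiapine, alprazolam, pregabalin, escitalopram).
AGENT_POOL <- function() {
  tibble::tribble(
    ~atc_code, ~drug_class, ~weight,
    "N05BA09", "benzodiazepine", 8,    # clonazepam
    "N05BA12", "benzodiazepine", 4,    # alprazolam
    "N05BA06", "benzodiazepine", 1.5,
    "N05BA01", "benzodiazepine", 1,
    "N05AH04", "antipsychotic", 6,     # quetiapine
    "N05AX08", "antipsychotic", 1.5,
    "N05AH03", "antipsychotic", 1,
    "N05AD01", "antipsychotic", 0.5,
    "N05AX12", "antipsychotic", 0.5,
    "N06AB10", "antidepressant", 4,    # escitalopram
    "N06AB06", "antidepressant", 2,
    "N06AB05", "antidepressant", 1,
    "N06AB03", "antidepressant", 1,
    "N06AA09", "antidepressant", 1,
    "N06AX16", "antidepressant", 1,
    "N06AX21", "antidepressant", 1,
    "N03AX16", "anti_epileptic", 4,    # pregabalin
    "N03AX12", "anti_epileptic", 1.5,
    "N03AX14", "anti_epileptic", 1,
    "N03AG01", "anti_epileptic", 0.5,
    "N03AF01", "anti_epileptic", 0.5,
    "N05CF02", "z_drug", 3,
    "N05CF01", "z_drug", 1,
    "N05CF04", "z_drug", 0.5,
    "N02AX02", "opioid", 2,
    "N02AA05", "opioid", 1,
    "N02AA01", "opioid", 0.5,
    "N02AB03", "opioid", 0.3
  )
}

CLASS_WEIGHTS <- c(antidepressant = 0.30, benzodiazepine = 0.27,
                   antipsychotic = 0.15, anti_epileptic = 0.12,
                   z_drug = 0.09, opioid = 0.07)

NOISE_CODES <- c("C09AA05", "C10AA01", "A02BC01", "C07AB07", "A10BA02",
                 "B01AC06", "C08CA01")

# months are absolute indices (year*12 + month-1), as in a month time_grid
MONTH0 <- function() 2021L * 12L  # 2021-01

monthly_hazard <- function(annual) 1 - (1 - annual)^(1 / 12)

#' Generate a synthetic baseline cohort
#'
#' One row per patient: demographics, diagnosis flags (anxiety and depression
#' mildly positively correlated), prior-year admissions, censoring periods
#' (absolute month indices; `NA` for none) and the latent ground-truth
#' polypharmacy indicator `poly_true` drawn from the logistic propensity.
#'
#' @param config a [generator_config()].
#' @return tibble cohort; reproducible given `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(config$n_patients)
  set.seed(config$seed)
  if (n == 0L) {
    return(tibble::tibble(patient_id = character(), age_years = numeric(),
                          age_band = factor(character(),
                                            c("60-69", "70-79", "80+")),
                          female = integer(),
                          death_period = integer(),
                          disaffiliation_period = integer(),
                          poly_true = integer()))
  }
  band <- sample(names(config$age_band_probs), n, TRUE, config$age_band_probs)
  age <- ifelse(band == "60-69", 60 + stats::runif(n) * 10,
         ifelse(band == "70-79", 70 + stats::runif(n) * 10,
                80 + stats::rexp(n, rate = 1 / 5)))
  age <- floor(age * 10) / 10  # truncate so rounding cannot cross a band edge
  p <- config$diagnosis_prevalences
  anxiety <- stats::rbinom(n, 1, p[["anxiety"]])
  # preserve the depressive marginal while enriching it among anxious patients
  p_dep_noanx <- (p[["depressive"]] - p[["anxiety"]] * config$depressive_given_anxiety) /
    (1 - p[["anxiety"]])
  if (p_dep_noanx < 0) stop("inconsistent anxiety/depression parameters", call. = FALSE)
  depressive <- stats::rbinom(n, 1, ifelse(anxiety == 1,
                                           config$depressive_given_anxiety,
                                           p_dep_noanx))
  flags <- list(anxiety = anxiety, depressive = depressive)
  for (nm in setdiff(names(p), c("anxiety", "depressive"))) {
    flags[[nm]] <- stats::rbinom(n, 1, p[[nm]])
  }
  cohort <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    age_years = age,
    age_band = factor(band, c("60-69", "70-79", "80+")),
    female = stats::rbinom(n, 1, config$female_prob))
  for (nm in names(flags)) cohort[[nm]] <- flags[[nm]]
  cohort$n_admissions <- stats::rpois(n, config$admission_mean)

  # censoring during 2021: competing geometric death / disaffiliation months
  dm <- stats::rgeom(n, monthly_hazard(config$death_rate))
  am <- stats::rgeom(n, monthly_hazard(config$disaffiliation_rate))
  cohort$death_period <- ifelse(dm <= 11 & dm <= am, MONTH0() + dm, NA_integer_)
  cohort$disaffiliation_period <-
    ifelse(am <= 11 & am < dm, MONTH0() + am, NA_integer_)

  beta <- config$true_log_odds
  eta <- config$intercept +
    beta[["age_band70-79"]] * (band == "70-79") +
    beta[["age_band80+"]] * (band == "80+") +
    beta[["female"]] * cohort$female +
    beta[["n_admissions"]] * cohort$n_admissions
  for (nm in names(p)) eta <- eta + beta[[nm]] * cohort[[nm]]
  cohort$poly_true <- stats::rbinom(n, 1, stats::plogis(eta))
  cohort
}

censor_period <- function(cohort) {
  pmin(cohort$death_period, cohort$disaffiliation_period, na.rm = TRUE)
}

# sample k distinct agents, classes drawn by CLASS_WEIGHTS
sample_regimen <- function(k, pool) {
  idx <- integer(0)
  guard <- 0L
  while (length(idx) < k && guard < 50L) {
    cl <- sample(names(CLASS_WEIGHTS), 1, prob = CLASS_WEIGHTS)
    cand <- which(pool$drug_class == cl & !seq_len(nrow(pool)) %in% idx)
    if (length(cand)) {
      idx <- c(idx, if (length(cand) == 1L) cand else
        sample(cand, 1, prob = pool$weight[cand]))
    }
    guard <- guard + 1L
  }
  pool$atc_code[idx]
}

# fill-month schedule for one agent: the anchor month always fills; other
# episode months fill with refill_prob, and a due fill is skipped (stockpiled
# the month before) with stockpile_prob
agent_fill_months <- function(months, anchor, refill_prob, stockpile_prob) {
  fill <- months == anchor |
    stats::runif(length(months)) < refill_prob * (1 - stockpile_prob)
  months[fill]
}

#' Generate synthetic prescription fills
#'
#' Builds the out-of-hospital fill stream implied by the cohort's ground
#' truth: polypharmacy episodes for true cases (prevalent cases anchored at
#' the index month, incident cases anchored at a geometrically decaying later
#' month), one-or-two-agent background use and staggered switchers among
#' controls, plus non-CNS noise fills. No fills are generated after a
#' patient's censoring month, and all fills stay inside the 2017-2021 window.
#'
#' @param cohort output of [generate_cohort()].
#' @param config the same [generator_config()].
#' @return tibble of fills: `patient_id`, `fill_date`, `atc_code`,
#'   `pills_per_box`, `mg_per_pill`, `n_boxes`.
#' @export
generate_fills <- function(cohort, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  pool <- AGENT_POOL()
  m0 <- MONTH0()
  last <- m0 + 11L          # 2021-12
  first_data <- (2017L) * 12L  # 2017-01
  cens <- censor_period(cohort)
  cens[is.na(cens)] <- last
  n <- nrow(cohort)
  if (n == 0L) {
    return(tibble::tibble(patient_id = character(), fill_date = as.Date(character()),
                          atc_code = character(), pills_per_box = integer(),
                          mg_per_pill = numeric(), n_boxes = integer()))
  }

  rows <- vector("list", n)
  is_case <- cohort$poly_true == 1
  u_role <- stats::runif(n)
  prevalent <- is_case & stats::runif(n) < config$prevalent_user_frac
  start_w <- config$incident_start_decay^(0:10)

  for (i in seq_len(n)) {
    pid <- cohort$patient_id[i]
    ci <- cens[i]
    agent <- character(0); month <- integer(0); boxes <- integer(0)

    if (is_case[i]) {
      k <- 3L + stats::rpois(1, config$extra_agent_mean)
      regimen <- sample_regimen(k, pool)
      anchor <- if (prevalent[i] || ci <= m0) m0 else {
        kmax <- min(11L, ci - m0)
        m0 + sample.int(kmax, 1, prob = start_w[seq_len(kmax)])
      }
      dur <- 1L + stats::rpois(1, config$episode_duration_mean)
      ep <- seq.int(anchor, min(anchor + dur - 1L, last, ci))
      pre <- if (prevalent[i]) {
        seq.int(max(anchor - (1L + stats::rpois(1, 3)), first_data), anchor - 1L)
      } else integer(0)
      for (a in regimen) {
        fm <- agent_fill_months(c(pre, ep), anchor,
                                config$refill_prob, config$stockpile_prob)
        agent <- c(agent, rep(a, length(fm))); month <- c(month, fm)
      }
    } else if (u_role[i] < config$switcher_prob && ci >= m0 + 2L) {
      # two agents stopped at m-2, a third started at m: triple concurrency
      # exists only when the grace period spans two months
      regimen <- sample_regimen(3L, pool)
      m <- m0 + sample.int(min(11L, ci - m0), 1) + 0L
      m <- max(m, m0 + 2L)
      ab_start <- max(m - 2L - stats::rpois(1, 3), first_data)
      ab <- seq.int(ab_start, m - 2L)
      c_end <- min(m + 1L + stats::rpois(1, 2), last, ci)
      cm <- agent_fill_months(seq.int(m, c_end), m,
                              config$refill_prob, config$stockpile_prob)
      agent <- c(rep(regimen[1], length(ab)), rep(regimen[2], length(ab)),
                 rep(regimen[3], length(cm)))
      month <- c(ab, ab, cm)
    } else if (u_role[i] < config$switcher_prob + config$background_user_prob) {
      k <- sample(1:2, 1, prob = c(0.7, 0.3))
      regimen <- sample_regimen(k, pool)
      s <- first_data + sample.int(last - first_data - 1L, 1)
      dur <- 1L + stats::rpois(1, 5)
      ep <- seq.int(s, min(s + dur - 1L, last, ci))
      for (a in regimen) {
        fm <- agent_fill_months(ep, s, config$refill_prob, config$stockpile_prob)
        agent <- c(agent, rep(a, length(fm))); month <- c(month, fm)
      }
    }

    n_noise <- stats::rpois(1, config$noise_fill_mean)
    if (n_noise > 0) {
      nm <- first_data + sample.int(max(ci - first_data, 1L), n_noise,
                                    replace = TRUE)
      agent <- c(agent, sample(NOISE_CODES, n_noise, TRUE))
      month <- c(month, nm)
    }
    if (length(agent)) {
      rows[[i]] <- list(patient_id = rep(pid, length(agent)),
                        atc_code = agent, month = month)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble::tibble(patient_id = character(), fill_date = as.Date(character()),
                          atc_code = character(), pills_per_box = integer(),
                          mg_per_pill = numeric(), n_boxes = integer()))
  }
  fills <- tibble::tibble(
    patient_id = unlist(lapply(rows, `[[`, "patient_id")),
    atc_code = unlist(lapply(rows, `[[`, "atc_code")),
    month = unlist(lapply(rows, `[[`, "month")))

  # pharmacy visit days: batched onto one visit with prob batch_prob
  visits <- fills |>
    dplyr::distinct(.data$patient_id, .data$month) |>
    dplyr::mutate(visit_day = sample.int(28L, dplyr::n(), replace = TRUE),
                  batched = stats::runif(dplyr::n()) < config$batch_prob)
  fills <- fills |>
    dplyr::left_join(visits, by = c("patient_id", "month")) |>
    dplyr::mutate(
      day = ifelse(.data$batched, .data$visit_day,
                   sample.int(28L, dplyr::n(), replace = TRUE)),
      fill_date = as.Date(sprintf("%04d-%02d-%02d", .data$month %/% 12L,
                                  .data$month %% 12L + 1L, .data$day)),
      pills_per_box = sample(c(30L, 60L), dplyr::n(), TRUE, c(0.8, 0.2)),
      mg_per_pill = sample(c(0.5, 1, 2, 5, 10, 20, 25, 50), dplyr::n(), TRUE),
      n_boxes = 1L + stats::rbinom(dplyr::n(), 1, config$stockpile_prob)) |>
    dplyr::arrange(.data$patient_id, .data$fill_date, .data$atc_code) |>
    dplyr::select("patient_id", "fill_date", "atc_code", "pills_per_box",
                  "mg_per_pill", "n_boxes")
  fills
}

#' Ground truth of a generator configuration
#'
#' Returns the quantities parameter-recovery tests compare against: the true
#' log odds ratios, the intercept, the marginal event probability (Monte
#' Carlo over the covariate distribution at large n with a fixed seed), the
#' agent pool and the RNG algorithm used.
#'
#' @param config a [generator_config()].
#' @param mc_n Monte-Carlo sample size for the marginal probability.
#' @return a list, serialisable to JSON and back without change.
#' @export
ground_truth <- function(config, mc_n = 200000L) {
  big <- config
  big$n_patients <- as.integer(mc_n)
  big$seed <- 987654L
  coh <- generate_cohort(big)
  list(
    true_log_odds = as.list(config$true_log_odds),
    intercept = config$intercept,
    marginal_event_prob = mean(coh$poly_true),
    prevalent_user_frac = config$prevalent_user_frac,
    class_weights = as.list(CLASS_WEIGHTS),
    rng = "Mersenne-Twister",
    seed = config$seed
  )
}

#' Simulate a full study data set to disk
#'
#' Writes `patients.csv`, `fills.csv` and `truth.json` (the ground truth) to
#' `out_dir`. `poly_true` is retained in `patients.csv` as a labelled
#' ground-truth column; the analysis pipeline never reads it as an input.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the cohort and fills tibbles and the paths.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  fills <- generate_fills(cohort, config)
  paths <- list(patients = file.path(out_dir, "patients.csv"),
                fills = file.path(out_dir, "fills.csv"),
                truth = file.path(out_dir, "truth.json"))
  readr::write_csv(cohort, paths$patients, progress = FALSE, na = "")
  readr::write_csv(fills, paths$fills, progress = FALSE, na = "")
  jsonlite::write_json(ground_truth(config), paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, fills = fills, paths = paths))
}
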