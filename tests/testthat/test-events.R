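three_agent_fills <- function(month = "2021-05") {
  rbind(fills_row("P1", paste0(month, "-03"), "N06AB10"),   # antidepressant
        fills_row("P1", paste0(month, "-10"), "N05AH04"),   # antipsychotic
        fills_row("P1", paste0(month, "-21"), "N05BA09"))   # benzodiazepine
}

detect_from <- function(fills, grace = 1L, threshold = 3L) {
  g <- month_grid()
  iv <- build_exposures(fills, rule = exposure_rule("month_grace", grace),
                        grid = g)
  detect_events(iv, threshold = threshold)
}

test_that("three concurrent agents of any class mix form one event per month", {
  ev <- detect_from(three_agent_fills())
  # month of fill plus one grace month -> two patient-period events
  expect_equal(nrow(ev), 2L)
  expect_identical(unique(ev$classes),
                   "antidepressant;antipsychotic;benzodiazepine")
  expect_equal(unique(ev$n_agents), 3L)

  # three distinct benzodiazepines qualify (single-class combination)
  benzos <- rbind(fills_row("P1", "2021-05-03", "N05BA09"),
                  fills_row("P1", "2021-05-10", "N05BA12"),
                  fills_row("P1", "2021-05-21", "N05BA01"))
  evb <- detect_from(benzos)
  expect_equal(nrow(evb), 2L)
  expect_identical(unique(evb$classes),
                   "benzodiazepine;benzodiazepine;benzodiazepine")

  # two agents only: below threshold, no event
  expect_equal(nrow(detect_from(three_agent_fills()[1:2, ])), 0L)

  # the same agent filled twice counts once
  dup <- rbind(three_agent_fills()[1:2, ],
               fills_row("P1", "2021-05-28", "N05AH04"))
  expect_equal(nrow(detect_from(dup)), 0L)
})

test_that("the event's agent set is the full concurrent set of the period", {
  f <- rbind(three_agent_fills(), fills_row("P1", "2021-05-27", "N03AX16"))
  ev <- detect_from(f)
  expect_equal(unique(ev$n_agents), 4L)
  expect_identical(strsplit(ev$agents[1], ";")[[1]],
                   sort(c("N06AB10", "N05AH04", "N05BA09", "N03AX16")))
})

test_that("event summaries obey the conservation laws", {
  # sizes 3 and 4 -> 7 medication records; two events share one patient
  f <- rbind(three_agent_fills("2021-02"),
             three_agent_fills("2021-08"),
             fills_row("P1", "2021-08-25", "N03AX16"),
             three_agent_fills("2021-11")[1:2, ],
             fills_row("P2", "2021-04-05", "N06AB10"),
             fills_row("P2", "2021-04-06", "N05CF02"),
             fills_row("P2", "2021-04-07", "N02AX02"))
  ev <- detect_from(f, grace = 0L)
  sm <- summarize_events(ev)
  expect_equal(sm$n_events, 3L)
  expect_equal(sm$n_patients_with_event, 2L)
  expect_equal(sm$n_medication_records, 3L + 4L + 3L)
  expect_equal(sum(sm$combination_frequency$n), sm$n_events)
  expect_equal(sum(sm$class_frequency$n), sm$n_medication_records)
  expect_equal(sum(sm$agent_frequency$n), sm$n_medication_records)
  # combination keys keep multiplicities: 2x antidep + 1x antipsychotic would
  # differ from 1x antidep + 2x antipsychotic
  expect_true("antidepressant;opioid;z_drug" %in%
                sm$combination_frequency$combination)

  empty <- summarize_events(detect_from(random_fills(0)))
  expect_equal(empty$n_events, 0L)
  expect_equal(empty$n_medication_records, 0L)
})

test_that("events at a higher threshold are a subset of the lower one", {
  set.seed(405)
  for (rep in 1:8) {
    fills <- random_fills(sample(10:40, 1), n_patients = 3)
    e3 <- detect_from(fills, threshold = 3L)
    e4 <- detect_from(fills, threshold = 4L)
    expect_true(all(paste(e4$patient_id, e4$period) %in%
                      paste(e3$patient_id, e3$period)))
  }
})

test_that("detect_events matches an exhaustive per-period recount oracle", {
  set.seed(406)
  g <- month_grid()
  for (rep in 1:15) {
    fills <- random_fills(sample(5:40, 1))
    grace <- sample(0:2, 1)
    ev <- detect_from(fills, grace = grace)
    want <- oracle_events(fills, g, grace, study_window(g, 2021))
    expect_identical(paste(ev$patient_id, ev$period, ev$n_agents),
                     paste(want$patient_id, want$period, want$n_agents))
  }
})

test_that("identical inputs give byte-identical event tables", {
  set.seed(407)
  fills <- random_fills(60)
  e1 <- detect_from(fills); e2 <- detect_from(fills)
  expect_identical(e1, e2)
})

test_that("time to first event uses index-anchored months with type-7 quantiles", {
  g <- month_grid()
  idx <- g$index_period
  ev0 <- detect_from(three_agent_fills("2021-01"))
  tt0 <- time_to_first_event(ev0)
  expect_equal(tt0$by_patient$months, 0)
  expect_equal(tt0$median, 0)

  # patients with first events at months 0, 3 and 7
  f <- rbind(three_agent_fills("2021-01"),
             local({x <- three_agent_fills("2021-04"); x$patient_id <- "P2"; x}),
             local({x <- three_agent_fills("2021-08"); x$patient_id <- "P3"; x}))
  tt <- time_to_first_event(detect_from(f))
  expect_equal(tt$median, 3)
  expect_equal(tt$iqr, c(1.5, 5))  # linear interpolation on {0,3,7}

  # agreement with an explicit sort-based quantile oracle on random spreads
  set.seed(408)
  for (rep in 1:5) {
    months <- sample(0:11, 30, replace = TRUE)
    evs <- do.call(rbind, lapply(seq_along(months), function(i) {
      x <- three_agent_fills(sprintf("2021-%02d", months[i] + 1))
      x$patient_id <- sprintf("Q%02d", i)
      x
    }))
    tt <- time_to_first_event(detect_from(evs, grace = 0L))
    expect_equal(tt$median, unname(stats::quantile(months, 0.5)))
    expect_equal(tt$iqr, unname(stats::quantile(months, c(0.25, 0.75))))
  }
})

test_that("mixed-rule interval lists are rejected", {
  g <- month_grid()
  iv <- build_exposures(three_agent_fills(), rule = exposure_rule("month_grace", 1L),
                        grid = g)
  iv$rule[1] <- "month_grace_2"
  expect_error(detect_events(iv), "mix exposure rules")
})
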