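test_that("a fill covers its month plus the grace period", {
  g <- month_grid()
  iv <- build_exposures(fills_row("P1", "2021-03-15", "N05BA09"),
                        rule = exposure_rule("month_grace", 1L), grid = g)
  expect_equal(nrow(iv), 1L)
  expect_identical(period_label(g, iv$start), "2021-03")
  expect_identical(period_label(g, iv$end), "2021-04")
  expect_identical(iv$drug_class, "benzodiazepine")

  # adjacent coverage merges into one maximal interval
  f2 <- rbind(fills_row("P1", "2021-03-02", "N05BA09"),
              fills_row("P1", "2021-04-20", "N05BA09"))
  iv2 <- build_exposures(f2, rule = exposure_rule("month_grace", 1L), grid = g)
  expect_equal(nrow(iv2), 1L)
  expect_identical(period_label(g, iv2$start), "2021-03")
  expect_identical(period_label(g, iv2$end), "2021-05")

  # a refill gap longer than the grace splits the exposure
  f3 <- rbind(fills_row("P1", "2021-01-02", "N05BA09"),
              fills_row("P1", "2021-06-20", "N05BA09"))
  iv3 <- build_exposures(f3, rule = exposure_rule("month_grace", 1L), grid = g)
  expect_equal(nrow(iv3), 2L)
})

test_that("empty and non-CNS inputs yield empty interval sets", {
  g <- month_grid()
  expect_equal(nrow(build_exposures(random_fills(0), grid = g)), 0L)
  iv <- build_exposures(fills_row("P1", "2021-03-15", "C09AA05"), grid = g)
  expect_equal(nrow(iv), 0L)
})

test_that("same-week fills cover exactly their ISO week", {
  rw <- exposure_rule("same_week")
  expect_equal(rw$grace, 0L)
  gw <- grid_for_rule(rw)
  # Wed 2021-03-03 and Mon 2021-03-15 fall in non-adjacent ISO weeks:
  # two single-week intervals, no grace coverage in between
  iv <- build_exposures(rbind(fills_row("P1", "2021-03-03", "N05BA09"),
                              fills_row("P1", "2021-03-15", "N05BA09")),
                        rule = rw, grid = gw)
  expect_equal(nrow(iv), 2L)
  expect_true(all(iv$start == iv$end))
  expect_identical(iv$start, date_to_period(gw, as.Date(c("2021-03-03",
                                                          "2021-03-15"))))
  # consecutive weeks merge into one maximal interval covering exactly them
  iv2 <- build_exposures(rbind(fills_row("P1", "2021-03-03", "N05BA09"),
                               fills_row("P1", "2021-03-08", "N05BA09")),
                         rule = rw, grid = gw)
  expect_equal(nrow(iv2), 1L)
  expect_equal(iv2$end - iv2$start, 1L)
})

test_that("fills outside the grid span or with bad dates are errors", {
  g <- month_grid()
  expect_error(build_exposures(fills_row("P1", "2016-12-31", "N05BA09"),
                               grid = g), "outside the grid span")
  expect_error(build_exposures(fills_row("P1", "not-a-date", "N05BA09"),
                               grid = g), "unparseable")
  rw <- exposure_rule("same_week")
  expect_error(build_exposures(random_fills(3), rule = rw, grid = g),
               "week-resolution grid")
})

test_that("concurrent_agents applies set semantics at a period", {
  g <- month_grid()
  f <- rbind(fills_row("P1", "2021-05-01", "N05BA09"),
             fills_row("P1", "2021-05-14", "N05BA09"),  # same agent twice
             fills_row("P1", "2021-05-20", "N05AH04"),
             fills_row("P1", "2021-05-25", "N06AB10"),
             fills_row("P1", "2021-03-01", "N03AX16"))  # expired by 2021-05
  iv <- build_exposures(f, rule = exposure_rule("month_grace", 1L), grid = g)
  p <- date_to_period(g, as.Date("2021-05-01"))
  got <- concurrent_agents(iv, "P1", p)
  expect_setequal(got$atc_code, c("N05BA09", "N05AH04", "N06AB10"))
  expect_equal(nrow(got), 3L)
  expect_error(concurrent_agents(iv, "P1", g$period_max + 1L), "outside")
})

test_that("exposure agrees with a brute-force coverage oracle", {
  set.seed(401)
  g <- month_grid()
  for (rep in 1:20) {
    fills <- random_fills(sample(1:25, 1))
    grace <- sample(0:2, 1)
    iv <- build_exposures(fills, rule = exposure_rule("month_grace", grace),
                          grid = g)
    # expand package intervals back to a coverage set
    got <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      data.frame(patient_id = iv$patient_id[i], atc_code = iv$atc_code[i],
                 period = iv$start[i]:iv$end[i])
    }))
    want <- oracle_coverage(fills, g, grace)
    key <- function(d) sort(paste(d$patient_id, d$atc_code, d$period))
    expect_identical(key(got), key(want))
    # merged intervals are pairwise disjoint and non-adjacent
    by_agent <- split(iv, paste(iv$patient_id, iv$atc_code))
    for (b in by_agent) {
      if (nrow(b) > 1L) expect_true(all(diff(b$start) > 0 &
                                        b$start[-1] > b$end[-nrow(b)] + 1L))
    }
  }
})

test_that("coverage is monotone in the grace period", {
  set.seed(402)
  g <- month_grid()
  cov_set <- function(iv) {
    unlist(lapply(seq_len(nrow(iv)), function(i) {
      paste(iv$patient_id[i], iv$atc_code[i], iv$start[i]:iv$end[i])
    }))
  }
  for (rep in 1:10) {
    fills <- random_fills(sample(1:20, 1))
    s1 <- cov_set(build_exposures(fills, rule = exposure_rule("month_grace", 1L),
                                  grid = g))
    s2 <- cov_set(build_exposures(fills, rule = exposure_rule("month_grace", 2L),
                                  grid = g))
    expect_true(all(s1 %in% s2))
  }
})

test_that("re-building from an interval's own implied fills changes nothing", {
  set.seed(403)
  g <- month_grid()
  fills <- random_fills(30)
  iv <- build_exposures(fills, rule = exposure_rule("month_grace", 0L), grid = g)
  implied <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
    data.frame(patient_id = iv$patient_id[i],
               fill_date = format(period_to_date(g, iv$start[i]:iv$end[i])),
               atc_code = iv$atc_code[i])
  }))
  iv2 <- build_exposures(implied, rule = exposure_rule("month_grace", 0L),
                         grid = g)
  expect_equal(as.data.frame(iv2), as.data.frame(iv))
})

test_that("a week with k concurrent agents implies a month with at least k", {
  set.seed(404)
  rw <- exposure_rule("same_week"); gw <- grid_for_rule(rw)
  gm <- month_grid()
  for (rep in 1:10) {
    fills <- random_fills(sample(5:30, 1))
    ivw <- build_exposures(fills, rule = rw, grid = gw)
    ivm <- build_exposures(fills, rule = exposure_rule("month_grace", 1L),
                           grid = gm)
    ww <- study_window(gw, 2021); wm <- study_window(gm, 2021)
    for (pid in unique(ivw$patient_id)) {
      kw <- vapply(ww, function(p) nrow(concurrent_agents(ivw, pid, p)),
                   integer(1))
      km <- vapply(wm, function(p) nrow(concurrent_agents(ivm, pid, p)),
                   integer(1))
      if (length(kw) && max(kw) > 0) expect_gte(max(km), max(kw))
    }
  }
})
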