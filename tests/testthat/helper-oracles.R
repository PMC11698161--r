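# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force coverage matrices for exposure,
# per-period recounts for events, bisection on binomial tail sums for the
# exact interval, and the cross-product ratio for 2x2 odds.

# brute-force (patient, agent, period) coverage from raw fills
oracle_coverage <- function(fills, grid, grace) {
  cls <- classify_atc(fills$atc_code)
  fills <- fills[!is.na(cls), , drop = FALSE]
  if (nrow(fills) == 0L) {
    return(data.frame(patient_id = character(), atc_code = character(),
                      period = integer()))
  }
  out <- list()
  for (i in seq_len(nrow(fills))) {
    m <- date_to_period(grid, as.Date(fills$fill_date[i]))
    for (p in m:min(m + grace, grid$period_max)) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = fills$patient_id[i],
        atc_code = toupper(fills$atc_code[i]), period = p)
    }
  }
  unique(do.call(rbind, out))
}

# per-period recount of polypharmacy patient-periods straight from fills
oracle_events <- function(fills, grid, grace, window, threshold = 3L) {
  cov <- oracle_coverage(fills, grid, grace)
  cov <- cov[cov$period %in% window, , drop = FALSE]
  if (nrow(cov) == 0L) {
    return(data.frame(patient_id = character(), period = integer(),
                      n_agents = integer()))
  }
  agg <- stats::aggregate(atc_code ~ patient_id + period, data = cov,
                          FUN = function(a) length(unique(a)))
  names(agg)[3] <- "n_agents"
  agg <- agg[agg$n_agents >= threshold, , drop = FALSE]
  agg[order(agg$patient_id, agg$period), , drop = FALSE]
}

# Clopper-Pearson by bisection on the binomial tail sums
oracle_cp <- function(x, n, alpha = 0.05, tol = 1e-12) {
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  low <- if (x == 0) 0 else
    bisect(function(p) sum(stats::dbinom(x:n, n, p)) - alpha / 2, 0, 1)
  high <- if (x == n) 1 else
    bisect(function(p) -(sum(stats::dbinom(0:x, n, p)) - alpha / 2), 0, 1)
  c(low = low, high = high)
}

# random small fill table on the 2017-2021 window
random_fills <- function(n_fills, n_patients = 5, n_agents = 6,
                         months = 48:59) {
  pool <- c("N05BA09", "N05BA12", "N05AH04", "N06AB10", "N03AX16",
            "N05CF02", "N02AX02", "C09AA05")[seq_len(min(n_agents, 8))]
  m <- sample(months, n_fills, replace = TRUE) + 2017L * 12L
  data.frame(
    patient_id = sample(sprintf("P%02d", seq_len(n_patients)), n_fills, TRUE),
    fill_date = sprintf("%04d-%02d-%02d", m %/% 12L, m %% 12L + 1L,
                        sample(28L, n_fills, TRUE)),
    atc_code = sample(pool, n_fills, TRUE))
}

fills_row <- function(pid, date, atc) {
  data.frame(patient_id = pid, fill_date = date, atc_code = atc)
}

month_grid <- function() time_grid("month")
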