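# Independent brute-force oracles, written with plain loops on purpose:
# they share no code path with the implementation they check.

METRIC_COLS <- c("m1_rx_count", "m2_patient_count", "m3_gt5day",
                 "m4_gt50medd", "m5_gt90medd")

in_window_dates <- function(dates, label) {
  w <- rxscorecard::quarter_window(label)
  dates >= w$start_date & dates < w$end_date
}

mk_rx <- function(rx_id, patient_id, prescriber_id, drug_code, upd, dpd, qty,
                  written_date, refills = 0L, authorizing_id = NA_character_) {
  tibble::tibble(
    rx_id = rx_id, patient_id = patient_id, prescriber_id = prescriber_id,
    authorizing_id = authorizing_id, drug_code = drug_code,
    units_per_dose = upd, max_doses_per_day = dpd, quantity_dispensed = qty,
    refills = as.integer(refills), written_date = as.Date(written_date)
  )
}

mk_providers <- function(ids, specialty = "GEN", division = "D1", role = "attending") {
  tibble::tibble(provider_id = ids, name = paste("Dr", ids), role = role,
                 specialty = specialty, division = division)
}

# linear interpolation between closest ranks, from first principles
oracle_quantile <- function(v, p) {
  x <- sort(v)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_thresholds <- function(values, k = 1.5, mult = 3, mode = "iqr_multiple") {
  q1 <- oracle_quantile(values, 0.25)
  q3 <- oracle_quantile(values, 0.75)
  iqr <- q3 - q1
  thr <- if (mode == "iqr_multiple") k * iqr else q3 + k * iqr
  c(outlier = thr, extreme = mult * thr)
}

oracle_status <- function(value, thr) {
  if (value > thr[["extreme"]]) "extreme_outlier"
  else if (value > thr[["outlier"]]) "outlier"
  else "within"
}

oracle_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

oracle_wilson <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z / (1 + z^2 / n) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  100 * c(center - half, center + half)
}

# one-prescription-at-a-time replay of the five metrics
oracle_metrics <- function(rxs, drugs, providers, quarter_label,
                           config = rxscorecard::default_run_config()) {
  w <- rxscorecard::quarter_window(quarter_label)
  as_of <- w$end_date - 1
  n <- nrow(rxs)
  attributed <- character(n)
  medd <- numeric(n); ds <- numeric(n)
  for (i in seq_len(n)) {
    attributed[i] <- if (!is.na(rxs$authorizing_id[i])) rxs$authorizing_id[i] else rxs$prescriber_id[i]
    d <- drugs[drugs$drug_code == rxs$drug_code[i], ]
    medd[i] <- d$strength_mg_per_unit * rxs$units_per_dose[i] *
      rxs$max_doses_per_day[i] * d$mme_factor
    ds[i] <- rxs$quantity_dispensed[i] / (rxs$units_per_dose[i] * rxs$max_doses_per_day[i])
  }
  chronic <- logical(n)
  for (i in seq_len(n)) {
    d0 <- rxs$written_date[i]
    cnt <- 0; active <- FALSE
    for (j in seq_len(n)) {
      if (j == i || rxs$patient_id[j] != rxs$patient_id[i]) next
      if (rxs$written_date[j] > d0 - config$lookback_days && rxs$written_date[j] <= d0) {
        cnt <- cnt + 1
      }
      if (rxs$written_date[j] <= d0 &&
          rxs$written_date[j] + ceiling(ds[j] * (rxs$refills[j] + 1)) >= d0) {
        active <- TRUE
      }
    }
    chronic[i] <- cnt >= config$chronic_min_rx && active
  }
  eligible <- character()
  for (p in providers$provider_id) {
    hit <- FALSE
    for (i in seq_len(n)) {
      if (attributed[i] == p && rxs$written_date[i] > as_of - config$lookback_days &&
          rxs$written_date[i] <= as_of) hit <- TRUE
    }
    if (hit) eligible <- c(eligible, p)
  }
  res <- NULL
  for (p in sort(eligible)) {
    in_q <- which(attributed == p & rxs$written_date >= w$start_date &
                    rxs$written_date < w$end_date)
    m1 <- length(in_q)
    m2 <- length(unique(rxs$patient_id[in_q]))
    m3 <- sum(!chronic[in_q] & ds[in_q] > config$day_supply_threshold)
    hit4 <- in_q[!chronic[in_q] & medd[in_q] > config$medd_acute_threshold]
    hit5 <- in_q[chronic[in_q] & medd[in_q] > config$medd_chronic_threshold]
    m4 <- if (config$metric4_unit == "patients") length(unique(rxs$patient_id[hit4])) else length(hit4)
    m5 <- if (config$metric5_unit == "patients") length(unique(rxs$patient_id[hit5])) else length(hit5)
    res <- rbind(res, data.frame(provider_id = p, m1_rx_count = m1,
                                 m2_patient_count = m2, m3_gt5day = m3,
                                 m4_gt50medd = m4, m5_gt90medd = m5))
  }
  res
}

fixture_pipeline <- function(config = rxscorecard::default_run_config()) {
  fx <- rxscorecard::generate_worked_fixture()
  derived <- rxscorecard::derive_prescriptions(fx$prescriptions, fx$drugs, config)
  metrics <- rxscorecard::compute_metrics(fx$prescriptions, derived, fx$providers,
                                          fx$quarter, config)
  thresholds <- rxscorecard::compute_thresholds(metrics, config)
  flags <- rxscorecard::flag_providers(metrics, thresholds)
  list(fx = fx, derived = derived, metrics = metrics,
       thresholds = thresholds, flags = flags)
}
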