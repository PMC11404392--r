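#' The five scorecard metrics per provider per quarter
#'
#' For every eligible provider (at least one attributed prescription in the 12
#' months ending on the quarter's last day — including providers with zero
#' in-quarter prescriptions, who appear as zero rows) computes:
#' \enumerate{
#'   \item `m1_rx_count` — opioid prescriptions attributed in-quarter;
#'   \item `m2_patient_count` — distinct patients prescribed to in-quarter;
#'   \item `m3_gt5day` — in-quarter prescriptions to nonchronic patients with a
#'     calculated day supply strictly over the day-supply threshold;
#'   \item `m4_gt50medd` — nonchronic MEDD exceedances over the acute threshold,
#'     counted as distinct patients or as prescriptions per `config$metric4_unit`;
#'   \item `m5_gt90medd` — chronic MEDD exceedances over the chronic threshold,
#'     unit per `config$metric5_unit`.
#' }
#' Chronicity is the patient's registry status on each prescription's written
#' date. Metrics are not mutually exclusive: one prescription may count toward
#' several. Prescriptions attributed to a provider absent from `providers` are
#' reported via [io_rejects()] on the result, never silently dropped.
#'
#' @param rxs Full prescription table (all history, not just the quarter; the
#'   lookback for eligibility and chronicity needs it).
#' @param derived Output of [derive_prescriptions()] for `rxs`.
#' @param providers Provider roster from [read_providers()].
#' @param quarter Quarter label (e.g. `"2021Q3"`) or one-row window tibble.
#' @param config A [default_run_config()] list.
#' @return Tibble: `provider_id, quarter, division, specialty, m1_rx_count,
#'   m2_patient_count, m3_gt5day, m4_gt50medd, m5_gt90medd`.
#' @export
compute_metrics <- function(rxs, derived, providers, quarter,
                            config = default_run_config()) {
  window <- if (is.character(quarter)) quarter_window(quarter) else quarter
  as_of <- window$end_date - 1

  rxs <- rxs %>% mutate(attributed_id = attribute_provider(rxs))
  eligible <- eligible_prescribers(rxs, as_of, config$lookback_days)
  known <- eligible[eligible %in% providers$provider_id]
  unknown <- setdiff(eligible, providers$provider_id)

  chron <- classify_rx_chronicity(rxs, derived, config)
  q <- rxs %>%
    mutate(chronicity = chron) %>%
    filter(in_window(written_date, window)) %>%
    left_join(derived, by = "rx_id")

  rej_rows <- q$attributed_id %in% unknown
  rejects <- tibble(row = which(rej_rows), id = q$rx_id[rej_rows],
                    reason = sprintf("unknown provider %s", q$attributed_id[rej_rows]))
  q <- q[!rej_rows, , drop = FALSE]

  count_unit <- function(df, unit) {
    if (nrow(df) == 0) return(tibble(attributed_id = character(), n = integer()))
    if (unit == "patients") {
      df %>% group_by(attributed_id) %>% summarise(n = n_distinct(patient_id), .groups = "drop")
    } else {
      df %>% count(attributed_id, name = "n")
    }
  }

  base <- tibble(provider_id = known)
  agg1 <- q %>% count(attributed_id, name = "m1_rx_count")
  agg2 <- q %>% group_by(attributed_id) %>%
    summarise(m2_patient_count = n_distinct(patient_id), .groups = "drop")
  agg3 <- q %>% filter(chronicity == "nonchronic", exceeds_day_threshold) %>%
    count(attributed_id, name = "m3_gt5day")
  agg4 <- count_unit(q %>% filter(chronicity == "nonchronic", exceeds_acute_medd),
                     config$metric4_unit) %>% rename(m4_gt50medd = n)
  agg5 <- count_unit(q %>% filter(chronicity == "chronic", exceeds_chronic_medd),
                     config$metric5_unit) %>% rename(m5_gt90medd = n)

  out <- base %>%
    left_join(agg1, by = c(provider_id = "attributed_id")) %>%
    left_join(agg2, by = c(provider_id = "attributed_id")) %>%
    left_join(agg3, by = c(provider_id = "attributed_id")) %>%
    left_join(agg4, by = c(provider_id = "attributed_id")) %>%
    left_join(agg5, by = c(provider_id = "attributed_id")) %>%
    mutate(dplyr::across(dplyr::starts_with("m"), ~ as.integer(tidyr::replace_na(.x, 0L)))) %>%
    left_join(providers %>% select(provider_id, division, specialty), by = "provider_id") %>%
    mutate(quarter = window$label) %>%
    select(provider_id, quarter, division, specialty, m1_rx_count, m2_patient_count,
           m3_gt5day, m4_gt50medd, m5_gt90medd) %>%
    arrange(provider_id)

  stopifnot(
    all(out$m2_patient_count <= out$m1_rx_count),
    all(out$m3_gt5day <= out$m1_rx_count)
  )
  set_rejects(out, rejects)
}

METRIC_NAMES <- c("m1_rx_count", "m2_patient_count", "m3_gt5day", "m4_gt50medd", "m5_gt90medd")
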