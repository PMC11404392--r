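#' Quartiles under linear interpolation
#'
#' First quartile, median, and third quartile of a numeric sequence under the
#' linear-interpolation-between-closest-ranks definition
#' ([stats::quantile()] type 7), pinned so thresholds reproduce across
#' implementations.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @examples
#' quartiles(c(1, 2, 3, 4, 5)) # 2 3 4
#' @export
quartiles <- function(values) {
  if (length(values) == 0 || all(is.na(values))) abort_fatal("quartiles: empty input")
  q <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Per-(division, specialty) outlier thresholds
#'
#' For each metric within each (division, specialty) group — zero-row providers
#' included in the distribution — computes quartiles, the IQR, and:
#' \itemize{
#'   \item mode `"iqr_multiple"` (default, the institution's stated rule):
#'     `outlier_threshold = outlier_k * IQR`;
#'   \item mode `"tukey_fence"`: `outlier_threshold = q3 + outlier_k * IQR`.
#' }
#' The extreme threshold is `extreme_multiplier * outlier_threshold`. Groups
#' smaller than `min_group_size` keep their thresholds but carry
#' `low_n_flag = TRUE` for auditability rather than being suppressed.
#' Thresholds are meant to be recomputed each quarter from that quarter's
#' distribution.
#'
#' @param metrics Output of [compute_metrics()].
#' @param config A [default_run_config()] list.
#' @return Tibble: `division, specialty, metric, n_providers, q1, median, q3,
#'   iqr, outlier_threshold, extreme_threshold, low_n_flag`.
#' @export
compute_thresholds <- function(metrics, config = default_run_config()) {
  if (nrow(metrics) == 0) {
    return(tibble(division = character(), specialty = character(),
                  metric = character(), n_providers = integer(), q1 = numeric(),
                  median = numeric(), q3 = numeric(), iqr = numeric(),
                  outlier_threshold = numeric(), extreme_threshold = numeric(),
                  low_n_flag = logical()))
  }
  long <- metrics %>%
    tidyr::pivot_longer(dplyr::all_of(METRIC_NAMES),
                        names_to = "metric", values_to = "value")
  out <- long %>%
    group_by(division, specialty, metric) %>%
    summarise(
      n_providers = n(),
      q1 = quartiles(value)[["q1"]],
      median = quartiles(value)[["median"]],
      q3 = quartiles(value)[["q3"]],
      .groups = "drop"
    ) %>%
    mutate(
      iqr = q3 - q1,
      outlier_threshold = if (config$threshold_mode == "iqr_multiple") {
        config$outlier_k * iqr
      } else {
        q3 + config$outlier_k * iqr
      },
      extreme_threshold = config$extreme_multiplier * outlier_threshold,
      low_n_flag = n_providers < config$min_group_size
    ) %>%
    arrange(division, specialty, metric)
  stopifnot(all(out$iqr >= 0), all(out$outlier_threshold >= 0),
            all(out$q1 <= out$median & out$median <= out$q3))
  out
}

#' Flag providers against their specialty thresholds
#'
#' Per provider and metric, compares the value to the group's thresholds with
#' strict `>`: strictly above the extreme threshold is `"extreme_outlier"`,
#' else strictly above the outlier threshold is `"outlier"`, else `"within"`.
#' A value equal to its threshold is within. `any_outlier` is TRUE when any
#' metric's status is not `"within"` (an extreme outlier is also an outlier).
#'
#' @param metrics Output of [compute_metrics()].
#' @param thresholds Output of [compute_thresholds()].
#' @return Tibble in long form: `provider_id, quarter, division, specialty,
#'   metric, value, outlier_threshold, extreme_threshold, status, any_outlier`.
#' @export
flag_providers <- function(metrics, thresholds) {
  long <- metrics %>%
    tidyr::pivot_longer(dplyr::all_of(METRIC_NAMES),
                        names_to = "metric", values_to = "value")
  missing_grp <- long %>%
    dplyr::anti_join(thresholds, by = c("division", "specialty", "metric"))
  if (nrow(missing_grp) > 0) {
    abort_fatal(sprintf("no thresholds for provider(s): %s",
                        paste(unique(missing_grp$provider_id), collapse = ", ")))
  }
  out <- long %>%
    left_join(thresholds %>%
                select(division, specialty, metric, outlier_threshold, extreme_threshold),
              by = c("division", "specialty", "metric")) %>%
    mutate(status = dplyr::case_when(
      value > extreme_threshold ~ "extreme_outlier",
      value > outlier_threshold ~ "outlier",
      TRUE ~ "within"
    )) %>%
    group_by(provider_id) %>%
    mutate(any_outlier = any(status != "within")) %>%
    ungroup() %>%
    arrange(provider_id, metric)
  out
}
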