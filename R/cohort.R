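#' Attribute each prescription to a provider
#'
#' A prescription counts toward the authorizing provider when one exists (as
#' for orders entered by advanced practice providers or house staff), otherwise
#' toward the ordering prescriber.
#'
#' @param rxs Prescription table.
#' @return Character vector of attributed provider ids, one per prescription.
#' @export
attribute_provider <- function(rxs) {
  ifelse(!is.na(rxs$authorizing_id), rxs$authorizing_id, rxs$prescriber_id)
}

#' Providers eligible for a scorecard
#'
#' A provider receives a scorecard iff at least one opioid prescription is
#' attributed to them with `written_date` in the trailing half-open window
#' `(as_of_date - lookback_days, as_of_date]`; providers with none are excluded.
#'
#' @param rxs Prescription table.
#' @param as_of_date `Date` the lookback ends on (inclusive).
#' @param lookback_days Window length in days (default 365).
#' @return Character vector of eligible provider ids (sorted, unique).
#' @export
eligible_prescribers <- function(rxs, as_of_date, lookback_days = 365) {
  as_of_date <- as.Date(as_of_date)
  if (nrow(rxs) == 0) return(character())
  in_window <- rxs$written_date > as_of_date - lookback_days & rxs$written_date <= as_of_date
  sort(unique(attribute_provider(rxs)[in_window]))
}

rx_active_until <- function(written_date, day_supply, refills) {
  written_date + ceiling(day_supply * (refills + 1))
}

#' Chronic-opioid-use registry snapshot
#'
#' A patient is on the chronic registry at `as_of_date` iff (a) they have at
#' least `chronic_min_rx` opioid prescriptions written in the trailing
#' `(as_of_date - lookback_days, as_of_date]` window, and (b) at least one of
#' their prescriptions is still active: `written_date +
#' ceiling(day_supply * (refills + 1)) >= as_of_date`.
#'
#' @param rxs Prescription table.
#' @param derived Output of [derive_prescriptions()] for the same rows.
#' @param as_of_date Snapshot `Date`.
#' @param config A [default_run_config()] list.
#' @return List with `as_of_date` and `chronic_patient_ids` (character vector).
#' @export
chronic_registry <- function(rxs, derived, as_of_date, config = default_run_config()) {
  as_of_date <- as.Date(as_of_date)
  d <- rxs %>%
    left_join(derived %>% select(rx_id, day_supply), by = "rx_id") %>%
    filter(written_date <= as_of_date)
  in_window <- d$written_date > as_of_date - config$lookback_days
  counts <- table(d$patient_id[in_window])
  enough <- names(counts)[counts >= config$chronic_min_rx]
  active <- unique(d$patient_id[
    rx_active_until(d$written_date, d$day_supply, d$refills) >= as_of_date
  ])
  list(as_of_date = as_of_date,
       chronic_patient_ids = sort(intersect(enough, active)))
}

#' Chronicity label of every prescription
#'
#' Labels each prescription `"chronic"` or `"nonchronic"` according to the
#' patient's registry status on the day the prescription was written, with the
#' prescription itself excluded from its own count (a patient's third-ever
#' prescription is still written to a nonchronic patient). Other prescriptions
#' written the same day do count.
#'
#' @inheritParams chronic_registry
#' @return Character vector, one label per row of `rxs`.
#' @export
classify_rx_chronicity <- function(rxs, derived, config = default_run_config()) {
  n <- nrow(rxs)
  label <- rep("nonchronic", n)
  if (n == 0) return(label)
  ds <- derived$day_supply[match(rxs$rx_id, derived$rx_id)]
  # only patients with more than chronic_min_rx prescriptions can ever qualify
  # (the record under classification is excluded from its own count)
  tab <- table(rxs$patient_id)
  candidates <- names(tab)[tab > config$chronic_min_rx]
  if (length(candidates) == 0) return(label)
  idx_all <- which(rxs$patient_id %in% candidates)
  for (pid in candidates) {
    idx <- which(rxs$patient_id == pid)
    wd <- rxs$written_date[idx]
    until <- rx_active_until(wd, ds[idx], rxs$refills[idx])
    for (k in seq_along(idx)) {
      d0 <- wd[k]
      others <- setdiff(seq_along(idx), k)
      n_in_year <- sum(wd[others] > d0 - config$lookback_days & wd[others] <= d0)
      any_active <- any(wd[others] <= d0 & until[others] >= d0)
      if (n_in_year >= config$chronic_min_rx && any_active) label[idx[k]] <- "chronic"
    }
  }
  label
}

#' Calendar quarter windows
#'
#' Half-open windows `[start, end)` tiling each requested year into four
#' disjoint, exhaustive calendar quarters.
#'
#' @param years Integer vector of calendar years.
#' @return Tibble: `label` (e.g. `"2021Q3"`), `start_date`, `end_date`.
#' @export
quarter_windows <- function(years) {
  grid <- expand.grid(q = 1:4, year = sort(unique(as.integer(years))))
  start <- as.Date(sprintf("%d-%02d-01", grid$year, (grid$q - 1) * 3 + 1))
  nxt_year <- ifelse(grid$q == 4, grid$year + 1, grid$year)
  nxt_month <- ifelse(grid$q == 4, 1, grid$q * 3 + 1)
  end <- as.Date(sprintf("%d-%02d-01", nxt_year, nxt_month))
  tibble(label = sprintf("%dQ%d", grid$year, grid$q), start_date = start, end_date = end)
}

#' Parse a quarter label into its window
#'
#' @param label Quarter label like `"2021Q3"`.
#' @return One-row tibble as in [quarter_windows()].
#' @export
quarter_window <- function(label) {
  m <- regmatches(label, regexec("^([0-9]{4})Q([1-4])$", label))[[1]]
  if (length(m) != 3) abort_fatal(sprintf("bad quarter label: %s (expected e.g. 2021Q3)", label))
  qw <- quarter_windows(as.integer(m[2]))
  qw[qw$label == label, , drop = FALSE]
}

in_window <- function(dates, window) {
  dates >= window$start_date & dates < window$end_date
}
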