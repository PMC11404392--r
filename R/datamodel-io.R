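#' @section File schemas:
#' Three CSV inputs drive a scorecard run:
#' \itemize{
#'   \item `prescriptions.csv`: `rx_id, patient_id, prescriber_id, authorizing_id,
#'     drug_code, units_per_dose, max_doses_per_day, quantity_dispensed, refills,
#'     written_date` (ISO-8601 dates; `authorizing_id` may be empty).
#'   \item `drugs.csv`: `drug_code, drug_name, opioid_class, strength_mg_per_unit,
#'     mme_factor` with `opioid_class` one of analgesic / antitussive / combination.
#'   \item `providers.csv`: `provider_id, name, role, specialty, division` with
#'     `role` one of attending / nurse_practitioner / physician_assistant / resident.
#' }
#' Rows that violate a record-level invariant are collected into a rejects table
#' (see [io_rejects()]), never silently dropped or imputed: the scorecards are
#' audit artifacts and every input row must be accounted for.
#' @name rx-io
NULL

PRESCRIPTION_COLS <- c(
  "rx_id", "patient_id", "prescriber_id", "authorizing_id", "drug_code",
  "units_per_dose", "max_doses_per_day", "quantity_dispensed", "refills",
  "written_date"
)
DRUG_COLS <- c("drug_code", "drug_name", "opioid_class", "strength_mg_per_unit", "mme_factor")
PROVIDER_COLS <- c("provider_id", "name", "role", "specialty", "division")
OPIOID_CLASSES <- c("analgesic", "antitussive", "combination")
PROVIDER_ROLES <- c("attending", "nurse_practitioner", "physician_assistant", "resident")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_fatal(sprintf(
      "%s: missing required column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

read_raw_csv <- function(path) {
  if (!file.exists(path)) abort_fatal(sprintf("file not found: %s", path))
  as_tibble(read.csv(path, colClasses = "character", comment.char = "#",
                     na.strings = character(), check.names = FALSE))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))
date_or_na <- function(x) as.Date(x, format = "%Y-%m-%d", optional = TRUE)

#' Row-level rejects of a reader
#'
#' Readers return the accepted records; rows that failed validation travel with
#' the result as a diagnostics table (`row`, `id`, `reason`).
#'
#' @param x A table returned by [read_prescriptions()] or [read_providers()].
#' @return A tibble of rejected rows (zero rows when everything parsed).
#' @export
io_rejects <- function(x) {
  attr(x, "rejects") %||% tibble(row = integer(), id = character(), reason = character())
}

set_rejects <- function(x, rejects) {
  attr(x, "rejects") <- rejects
  x
}

#' Read the opioid drug conversion table
#'
#' @param path Path to `drugs.csv`.
#' @return Tibble keyed by `drug_code` with typed columns. Duplicated codes,
#'   negative strengths or MME factors, and unknown opioid classes are fatal
#'   schema errors; an empty table is allowed with a warning.
#' @export
read_drug_table <- function(path) {
  raw <- check_schema(read_raw_csv(path), DRUG_COLS, "drug table")
  if (nrow(raw) == 0) {
    warning("drug table is empty", call. = FALSE)
    return(tibble(drug_code = character(), drug_name = character(),
                  opioid_class = character(), strength_mg_per_unit = numeric(),
                  mme_factor = numeric()))
  }
  dup <- raw$drug_code[duplicated(raw$drug_code)]
  if (length(dup) > 0) {
    abort_fatal(sprintf("duplicate drug_code: %s", paste(unique(dup), collapse = ", ")))
  }
  out <- raw %>%
    mutate(
      strength_mg_per_unit = num_or_na(strength_mg_per_unit),
      mme_factor = num_or_na(mme_factor)
    )
  bad_class <- setdiff(unique(out$opioid_class), OPIOID_CLASSES)
  if (length(bad_class) > 0) {
    abort_fatal(sprintf("unknown opioid_class: %s", paste(bad_class, collapse = ", ")))
  }
  if (any(is.na(out$strength_mg_per_unit) | out$strength_mg_per_unit < 0)) {
    abort_fatal("strength_mg_per_unit must be a number >= 0 for every drug")
  }
  if (any(is.na(out$mme_factor) | out$mme_factor < 0)) {
    abort_fatal("mme_factor must be a number >= 0 for every drug")
  }
  out
}

#' Read the provider roster
#'
#' @param path Path to `providers.csv`.
#' @return Tibble keyed by `provider_id`. Duplicate ids are fatal; rows with an
#'   empty specialty, division, or unknown role are rejected (see [io_rejects()]).
#' @export
read_providers <- function(path) {
  raw <- check_schema(read_raw_csv(path), PROVIDER_COLS, "provider roster")
  dup <- raw$provider_id[duplicated(raw$provider_id)]
  if (length(dup) > 0) {
    abort_fatal(sprintf("duplicate provider_id: %s", paste(unique(dup), collapse = ", ")))
  }
  reason <- rep(NA_character_, nrow(raw))
  reason[!nzchar(trimws(raw$specialty))] <- "empty specialty"
  reason[!nzchar(trimws(raw$division))] <- "empty division"
  reason[!raw$role %in% PROVIDER_ROLES] <- "unknown role"
  reason[!nzchar(trimws(raw$provider_id))] <- "empty provider_id"
  keep <- is.na(reason)
  rejects <- tibble(row = which(!keep), id = raw$provider_id[!keep], reason = reason[!keep])
  set_rejects(raw[keep, , drop = FALSE], rejects)
}

#' Read prescription-level records
#'
#' Parses and validates one row per ambulatory opioid prescription. A missing
#' column is a fatal schema error; an individual row with an unparseable date
#' or number, a non-positive quantity/sig, a negative refill count, or a
#' `drug_code` that does not resolve against `drug_table` is placed in the
#' rejects table with the reason, and the remaining rows are returned.
#'
#' @param path Path to `prescriptions.csv`.
#' @param drug_table Table from [read_drug_table()].
#' @return Tibble of accepted prescriptions (typed columns, `written_date` as
#'   `Date`, `authorizing_id` `NA` when absent), with rejects attached.
#' @export
read_prescriptions <- function(path, drug_table) {
  raw <- check_schema(read_raw_csv(path), PRESCRIPTION_COLS, "prescriptions")
  out <- raw %>%
    mutate(
      authorizing_id = ifelse(nzchar(trimws(authorizing_id)), authorizing_id, NA_character_),
      units_per_dose = num_or_na(units_per_dose),
      max_doses_per_day = num_or_na(max_doses_per_day),
      quantity_dispensed = num_or_na(quantity_dispensed),
      refills = num_or_na(refills),
      written_date = date_or_na(written_date)
    )
  reason <- rep(NA_character_, nrow(out))
  numeric_bad <- is.na(out$units_per_dose) | is.na(out$max_doses_per_day) |
    is.na(out$quantity_dispensed) | is.na(out$refills)
  reason[numeric_bad] <- "unparseable numeric field"
  reason[is.na(reason) & is.na(out$written_date)] <- "unparseable written_date"
  reason[is.na(reason) & out$quantity_dispensed <= 0] <- "quantity_dispensed must be > 0"
  reason[is.na(reason) & out$units_per_dose <= 0] <- "units_per_dose must be > 0"
  reason[is.na(reason) & out$max_doses_per_day <= 0] <- "max_doses_per_day must be > 0"
  reason[is.na(reason) & out$refills < 0] <- "refills must be >= 0"
  reason[is.na(reason) & !out$drug_code %in% drug_table$drug_code] <- "unresolvable drug_code"
  keep <- is.na(reason)
  rejects <- tibble(row = which(!keep), id = raw$rx_id[!keep], reason = reason[!keep])
  recs <- out[keep, , drop = FALSE]
  recs$refills <- as.integer(recs$refills)
  set_rejects(recs, rejects)
}

#' Default scorecard run configuration
#'
#' The guideline constants and analysis modes of a quarterly run. Defaults:
#' a prescription is flagged when its calculated day supply strictly exceeds
#' 5 days (nonchronic), its MEDD strictly exceeds 50 (nonchronic) or 90
#' (chronic); a patient is chronic with >= 3 prescriptions in the trailing
#' 365 days plus an active prescription; outlier thresholds are
#' `outlier_k * IQR` per (division, specialty) with extremes at 3x that.
#'
#' @param ... Named overrides of any default field.
#' @return A `rx_run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    quarter = NULL,
    threshold_mode = "iqr_multiple",
    outlier_k = 1.5,
    extreme_multiplier = 3,
    metric4_unit = "patients",
    metric5_unit = "patients",
    day_supply_threshold = 5,
    medd_acute_threshold = 50,
    medd_chronic_threshold = 90,
    chronic_min_rx = 3,
    lookback_days = 365,
    min_group_size = 5,
    random_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort_fatal(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(
    cfg$threshold_mode %in% c("iqr_multiple", "tukey_fence"),
    cfg$metric4_unit %in% c("patients", "prescriptions"),
    cfg$metric5_unit %in% c("patients", "prescriptions")
  )
  for (f in c("outlier_k", "extreme_multiplier", "day_supply_threshold",
              "medd_acute_threshold", "medd_chronic_threshold",
              "chronic_min_rx", "lookback_days")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] <= 0) {
      abort_fatal(sprintf("config field %s must be a positive number", f))
    }
  }
  if (!is_count(cfg$min_group_size)) abort_fatal("min_group_size must be a non-negative integer")
  structure(cfg, class = "rx_run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Fields mirror [default_run_config()]; absent fields take their defaults.
#'
#' @param path `.json`, `.yaml`, or `.yml` file.
#' @return A `rx_run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_fatal(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort_fatal(sprintf("unsupported config format: .%s (use JSON or YAML)", ext))
  )
  do.call(default_run_config, vals)
}

#' @export
print.rx_run_config <- function(x, ...) {
  cat("<rx_run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Write a table as CSV with config provenance comments
#'
#' Writes `# key: value` comment lines recording the analysis modes above a
#' standard CSV body, so every stage output records how it was produced.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Optional `rx_run_config` whose choices go in the header.
#' @export
write_stage_csv <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(config)) {
    for (nm in c("threshold_mode", "outlier_k", "extreme_multiplier",
                 "metric4_unit", "metric5_unit")) {
      writeLines(sprintf("# %s: %s", nm, config[[nm]]), con)
    }
  }
  df <- as.data.frame(df)
  if ("written_date" %in% names(df)) df$written_date <- format(df$written_date, "%Y-%m-%d")
  write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write prescriptions / providers / drug tables back to CSV
#'
#' Round-trip companions to the readers: reading a written file reproduces the
#' records field-for-field.
#'
#' @param df Table of records.
#' @param path Output path.
#' @export
write_records_csv <- function(df, path) {
  out <- as.data.frame(df)
  if ("written_date" %in% names(out)) out$written_date <- format(out$written_date, "%Y-%m-%d")
  if ("authorizing_id" %in% names(out)) {
    out$authorizing_id[is.na(out$authorizing_id)] <- ""
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
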