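#' Morphine equivalent daily dose of one prescription
#'
#' MEDD is the daily opioid dose converted to oral-morphine milligrams:
#' `strength_mg_per_unit * units_per_dose * max_doses_per_day * mme_factor`.
#' PRN sigs contribute their maximum permitted frequency, the conservative
#' convention in MME audit practice.
#'
#' @param rx One prescription record (list or one-row data frame).
#' @param drug Matching drug table entry.
#' @return MEDD in oral-morphine mg/day (finite, `>= 0`).
#' @examples
#' # oxycodone 5 mg tabs, 1 tab four times daily, factor 1.5 -> 30 MEDD
#' @export
medd_of_prescription <- function(rx, drug) {
  if (is.null(drug$mme_factor) || any(is.na(drug$mme_factor))) {
    abort_fatal(sprintf("missing mme_factor for drug_code %s", drug$drug_code))
  }
  stopifnot(rx$units_per_dose > 0, rx$max_doses_per_day > 0)
  medd <- drug$strength_mg_per_unit * rx$units_per_dose * rx$max_doses_per_day * drug$mme_factor
  stopifnot(is.finite(medd), medd >= 0)
  medd
}

#' Calculated day supply of one prescription
#'
#' Duration implied by the quantity and the dosage instructions:
#' `quantity_dispensed / (units_per_dose * max_doses_per_day)`, real-valued and
#' never rounded. Refills are excluded: the prescription itself, not its
#' renewals, is the audited act.
#'
#' @param rx One prescription record.
#' @return Day supply in days (`> 0`).
#' @export
calculated_day_supply <- function(rx) {
  denom <- rx$units_per_dose * rx$max_doses_per_day
  if (any(denom <= 0)) abort_fatal("units_per_dose * max_doses_per_day must be > 0")
  rx$quantity_dispensed / denom
}

#' Per-prescription derived dose quantities and guideline flags
#'
#' Joins prescriptions to the drug table and computes, for every prescription,
#' its MEDD, calculated day supply, and the three guideline-exceedance flags.
#' All flags use strict `>` against the configured thresholds, so a boundary
#' value (exactly a 5-day supply, exactly 50 MEDD) is compliant.
#'
#' @param rxs Prescription table from [read_prescriptions()].
#' @param drug_table Drug table from [read_drug_table()].
#' @param config A [default_run_config()] list.
#' @return Tibble: `rx_id, medd, day_supply, exceeds_day_threshold,
#'   exceeds_acute_medd, exceeds_chronic_medd`.
#' @export
derive_prescriptions <- function(rxs, drug_table, config = default_run_config()) {
  unresolved <- setdiff(unique(rxs$drug_code), drug_table$drug_code)
  if (length(unresolved) > 0) {
    abort_fatal(sprintf("unresolvable drug_code: %s", paste(unresolved, collapse = ", ")))
  }
  joined <- rxs %>%
    left_join(drug_table %>% select(drug_code, strength_mg_per_unit, mme_factor),
              by = "drug_code")
  out <- joined %>%
    mutate(
      medd = strength_mg_per_unit * units_per_dose * max_doses_per_day * mme_factor,
      day_supply = quantity_dispensed / (units_per_dose * max_doses_per_day),
      exceeds_day_threshold = day_supply > config$day_supply_threshold,
      exceeds_acute_medd = medd > config$medd_acute_threshold,
      exceeds_chronic_medd = medd > config$medd_chronic_threshold
    ) %>%
    select(rx_id, medd, day_supply, exceeds_day_threshold,
           exceeds_acute_medd, exceeds_chronic_medd)
  stopifnot(all(out$medd >= 0), all(out$day_supply > 0), all(is.finite(out$medd)))
  out
}
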