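#' Hand-auditable worked fixture
#'
#' A small, fully deterministic dataset (41 prescriptions, 10 providers across
#' two specialties of one division, scored quarter 2021Q3) whose five metrics,
#' thresholds, and flags can be verified by hand. It deliberately covers every
#' boundary the pipeline defines:
#' \itemize{
#'   \item a prescription with exactly a 5.0-day calculated supply (compliant
#'     under strict `>`);
#'   \item a prescription at exactly 50 MEDD (compliant);
#'   \item a patient whose third-ever prescription is still written to a
#'     nonchronic patient (self-exclusion), and whose fourth is chronic;
#'   \item attribution of a resident's order to its authorizing attending;
#'   \item an eligible provider with zero in-quarter prescriptions (zero row);
#'   \item `within`, `outlier`, and `extreme_outlier` statuses, including an
#'     extreme flag born of a zero-IQR group.
#' }
#' The expected per-provider metrics and flag statuses were computed by hand
#' once and ship as `inst/extdata/worked/expected_metrics.csv` and
#' `expected_flags.csv`.
#'
#' @param out_dir Optional directory to write the four CSVs to.
#' @return List of tibbles `providers`, `drugs`, `prescriptions`, and the
#'   scored `quarter` label.
#' @export
generate_worked_fixture <- function(out_dir = NULL) {
  providers <- tibble(
    provider_id = c(sprintf("P%d", 1:9), "P8R"),
    name = c(sprintf("Provider %d", 1:9), "Resident 8R"),
    role = c(rep("attending", 7), "nurse_practitioner", "attending", "resident"),
    specialty = c(rep("EM", 5), rep("IM", 4), "IM"),
    division = "Metro"
  )
  drugs <- default_drug_table()

  rx <- function(rx_id, patient_id, prescriber_id, drug_code, upd, dpd, qty,
                 written_date, refills = 0L, authorizing_id = NA_character_) {
    tibble(rx_id = rx_id, patient_id = patient_id, prescriber_id = prescriber_id,
           authorizing_id = authorizing_id, drug_code = drug_code,
           units_per_dose = upd, max_doses_per_day = dpd,
           quantity_dispensed = qty, refills = as.integer(refills),
           written_date = as.Date(written_date))
  }

  p5_dates <- as.Date("2021-07-01") + seq(0, 76, by = 4) # 20 dates inside Q3
  prescriptions <- bind_rows(
    ## EM -----------------------------------------------------------------
    rx("R01", "T01", "P1", "TRA50", 1, 3, 12, "2021-07-05"),           # medd 15, ds 4
    rx("R02", "T02", "P2", "OXY5", 1, 4, 20, "2021-07-06"),            # ds exactly 5.0
    rx("R03", "T03", "P2", "HYD10", 1, 4, 16, "2021-07-07"),           # medd 40, ds 4
    rx("R04", "T04", "P3", "HYD10", 1, 5, 20, "2021-07-08"),           # medd exactly 50
    rx("R05", "T05", "P3", "OXY5", 1, 4, 24, "2021-07-09"),            # ds 6 -> m3
    rx("R06", "T06", "P3", "MOR15", 1, 4, 30, "2021-07-12"),           # medd 60, ds 7.5 -> m3+m4
    # chronic patient CP1: three 30-day history fills, third with 2 refills
    rx("H1", "CP1", "P4", "MOR15", 1, 2, 60, "2021-01-10"),
    rx("H2", "CP1", "P4", "MOR15", 1, 2, 60, "2021-03-10"),
    rx("H3", "CP1", "P4", "MOR15", 1, 2, 60, "2021-05-10", refills = 2),
    rx("R07", "CP1", "P4", "MOR15", 2, 4, 240, "2021-07-15"),          # chronic, medd 120 -> m5
    # patient CP2: third rx still nonchronic (self-excluded), fourth chronic
    rx("G1", "CP2", "P4", "OXY5", 1, 4, 20, "2021-06-01"),
    rx("G2", "CP2", "P4", "OXY5", 1, 4, 12, "2021-07-05"),
    rx("G3", "CP2", "P4", "OXY5", 1, 4, 12, "2021-08-02", refills = 9),
    rx("G4", "CP2", "P4", "HYD10", 1, 4, 16, "2021-09-01"),            # chronic, medd 40
    rx("R08", "T07", "P4", "OXY5", 1, 6, 36, "2021-07-20"),            # medd 45, ds 6 -> m3
    rx("R09", "T08", "P4", "HM4", 1, 4, 8, "2021-07-21"),              # medd 64 -> m4
    # P5: 20 prescriptions to 10 patients, no exceedances
    rx(sprintf("R%02d", 10:29), rep(sprintf("T%02d", 9:18), each = 2),
       "P5", "TRA50", 1, 4, 16, p5_dates),
    ## IM -----------------------------------------------------------------
    rx("R30", "T30", "P6", "OXY5", 1, 4, 12, "2021-05-20"),            # eligibility only
    rx("R31", "T31", "P7", "HYD10", 1, 3, 12, "2021-08-10", authorizing_id = "P7"),
    rx("R32", "T32", "P8R", "OXY5", 1, 4, 40, "2021-08-11", authorizing_id = "P8"), # ds 10 -> m3
    rx("R33", "T33", "P9", "TRA50", 1, 2, 8, "2021-08-12"),
    rx("R34", "T34", "P9", "TRA50", 1, 2, 8, "2021-08-13")
  )

  out <- list(providers = providers, drugs = drugs,
              prescriptions = prescriptions, quarter = "2021Q3")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records_csv(providers, file.path(out_dir, "providers.csv"))
    write_records_csv(drugs, file.path(out_dir, "drugs.csv"))
    write_records_csv(prescriptions, file.path(out_dir, "prescriptions.csv"))
  }
  out
}

#' Committed hand-computed expectations for the worked fixture
#'
#' @param what `"metrics"` or `"flags"`.
#' @return Tibble read from the committed expectation CSV.
#' @export
worked_fixture_expectations <- function(what = c("metrics", "flags")) {
  what <- match.arg(what)
  path <- system.file("extdata", "worked", paste0("expected_", what, ".csv"),
                      package = "rxscorecard")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
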