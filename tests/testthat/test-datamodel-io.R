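drug_csv <- function(dir, rows = c("MOR15,morphine 15,analgesic,15,1",
                                   "OXY5,oxycodone 5,analgesic,5,1.5")) {
  path <- file.path(dir, "drugs.csv")
  writeLines(c("drug_code,drug_name,opioid_class,strength_mg_per_unit,mme_factor", rows), path)
  path
}

rx_header <- "rx_id,patient_id,prescriber_id,authorizing_id,drug_code,units_per_dose,max_doses_per_day,quantity_dispensed,refills,written_date"

test_that("well-formed prescriptions parse fully; bad rows land in rejects with reasons", {
  dir <- withr::local_tempdir()
  drugs <- read_drug_table(drug_csv(dir))
  path <- file.path(dir, "rx.csv")
  writeLines(c(rx_header,
               "R1,PA,P1,,OXY5,1,4,20,0,2021-07-01",
               "R2,PB,P2,P9,MOR15,2,3,12,1,2021-07-02",
               "R3,PC,P1,,OXY5,1,4,30,0,2021-07-03"), path)
  got <- read_prescriptions(path, drugs)
  expect_equal(nrow(got), 3)
  expect_equal(nrow(io_rejects(got)), 0)
  expect_s3_class(got$written_date, "Date")
  expect_true(is.na(got$authorizing_id[1]) && got$authorizing_id[2] == "P9")

  writeLines(c(rx_header,
               "R1,PA,P1,,OXY5,1,4,0,0,2021-07-01",      # zero quantity
               "R2,PB,P1,,XXX,1,4,10,0,2021-07-02",      # unknown drug
               "R3,PC,P1,,OXY5,1,4,10,0,not-a-date",     # bad date
               "R4,PD,P1,,OXY5,1,4,10,0,2021-07-04"), path)
  got <- read_prescriptions(path, drugs)
  rej <- io_rejects(got)
  expect_equal(nrow(got), 1)
  expect_equal(nrow(rej), 3)                              # conservation: 1 + 3 = 4
  expect_match(rej$reason[rej$id == "R1"], "quantity")
  expect_equal(rej$reason[rej$id == "R2"], "unresolvable drug_code")
  expect_match(rej$reason[rej$id == "R3"], "written_date")
})

test_that("missing required column is a fatal schema error", {
  dir <- withr::local_tempdir()
  drugs <- read_drug_table(drug_csv(dir))
  path <- file.path(dir, "rx.csv")
  writeLines(c("rx_id,patient_id,prescriber_id", "R1,PA,P1"), path)
  expect_error(read_prescriptions(path, drugs), "missing required column")
})

test_that("drug table: lookup works, duplicates and negatives are fatal, empty warns", {
  dir <- withr::local_tempdir()
  drugs <- read_drug_table(drug_csv(dir))
  expect_equal(drugs$mme_factor[drugs$drug_code == "MOR15"], 1)
  expect_error(read_drug_table(drug_csv(dir, c("A,x,analgesic,5,1", "A,y,analgesic,5,1"))),
               "duplicate drug_code: A")
  expect_error(read_drug_table(drug_csv(dir, "A,x,analgesic,5,-1")), "mme_factor")
  expect_warning(empty <- read_drug_table(drug_csv(dir, character())), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("provider roster: duplicate id fatal, empty specialty rejected, groupable", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "prov.csv")
  writeLines(c("provider_id,name,role,specialty,division",
               "P1,A,attending,EM,D1", "P2,B,resident,EM,D1",
               "P3,C,attending,IM,D1", "P4,D,nurse_practitioner,IM,D2",
               "P5,E,attending,,D1"), path)
  got <- read_providers(path)
  expect_equal(nrow(got), 4)
  expect_equal(io_rejects(got)$reason, "empty specialty")
  expect_equal(nrow(unique(got[, c("division", "specialty")])), 3)

  writeLines(c("provider_id,name,role,specialty,division",
               "P1,A,attending,EM,D1", "P1,B,attending,EM,D1"), path)
  expect_error(read_providers(path), "duplicate provider_id: P1")
})

test_that("record round-trip: write then read reproduces fields exactly", {
  dir <- withr::local_tempdir()
  drugs <- read_drug_table(drug_csv(dir))
  rxs <- mk_rx(c("R1", "R2"), c("PA", "PB"), c("P1", "P2"), c("OXY5", "MOR15"),
               c(1, 2), c(4, 3), c(20, 12), c("2021-07-01", "2021-07-02"),
               refills = c(0L, 2L), authorizing_id = c(NA, "P9"))
  path <- file.path(dir, "rt.csv")
  write_records_csv(rxs, path)
  back <- read_prescriptions(path, drugs)
  expect_equal(as.data.frame(back), as.data.frame(rxs), ignore_attr = TRUE)
  expect_equal(nrow(io_rejects(back)), 0)
})

test_that("run config reads JSON and YAML, rejects bad values and unknown fields", {
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(outlier_k = 2, threshold_mode = "tukey_fence"), jp,
                       auto_unbox = TRUE)
  cfg <- read_run_config(jp)
  expect_equal(cfg$outlier_k, 2)
  expect_equal(cfg$threshold_mode, "tukey_fence")
  expect_equal(cfg$medd_acute_threshold, 50)   # defaults fill in

  yp <- file.path(dir, "cfg.yaml")
  writeLines(c("day_supply_threshold: 7", "metric4_unit: prescriptions"), yp)
  cfg2 <- read_run_config(yp)
  expect_equal(cfg2$day_supply_threshold, 7)
  expect_equal(cfg2$metric4_unit, "prescriptions")

  expect_error(default_run_config(outlier_k = -1), "positive")
  expect_error(default_run_config(nonsense = 1), "unknown config field")
})
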