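small_cfg <- function(...) {
  sim_config(n_specialties = 6, providers_per_specialty = 10, n_quarters = 3,
             history_quarters = 2, seed = 404, ...)
}

test_that("generation is deterministic under a fixed seed and respects the configured shape", {
  a <- simulate_prescribing_data(small_cfg())
  b <- simulate_prescribing_data(small_cfg())
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$truth, b$truth)
  active <- 6 * 10
  expect_equal(nrow(a$providers), active + round(0.1 * active))
  expect_equal(length(unique(a$providers$specialty)), 6)
  expect_equal(length(unique(a$providers$division)), 3)
  expect_equal(a$quarters, c("2020Q3", "2020Q4", "2021Q1"))
  c_diff <- simulate_prescribing_data(small_cfg(seed = 405))
  expect_false(identical(a$prescriptions, c_diff$prescriptions))
})

test_that("zero outlier fraction injects no outliers; files pass the readers with no rejects", {
  dir <- withr::local_tempdir()
  d <- simulate_prescribing_data(small_cfg(outlier_fraction = 0), out_dir = dir)
  expect_equal(sum(d$truth$entity_type == "outlier_provider"), 0)
  drugs <- read_drug_table(file.path(dir, "drugs.csv"))
  provs <- read_providers(file.path(dir, "providers.csv"))
  rxs <- read_prescriptions(file.path(dir, "prescriptions.csv"), drugs)
  expect_equal(nrow(io_rejects(provs)), 0)
  expect_equal(nrow(io_rejects(rxs)), 0)
  expect_equal(nrow(rxs), nrow(d$prescriptions))
})

test_that("per-provider prescription volume tracks the configured rate distribution", {
  cfg <- sim_config(n_specialties = 20, providers_per_specialty = 30,
                    specialty_sdlog = 0, outlier_fraction = 0, trend_ratio = 1,
                    chronic_rx_fraction = 0, n_quarters = 3, history_quarters = 0,
                    inactive_fraction = 0, seed = 99)
  d <- simulate_prescribing_data(cfg)
  mean_per_quarter <- nrow(d$prescriptions) / (600 * 3)
  expected <- exp(cfg$rate_meanlog + cfg$rate_sdlog^2 / 2)
  expect_lt(abs(mean_per_quarter - expected) / expected, 0.05)
})

test_that("generated exceedance fractions match the configured fractions", {
  d <- simulate_prescribing_data(sim_config(n_specialties = 10,
                                            providers_per_specialty = 20,
                                            n_quarters = 3, history_quarters = 1,
                                            seed = 31))
  cfg <- default_run_config()
  der <- derive_prescriptions(d$prescriptions, d$drugs, cfg)
  chronic_pat <- d$truth$entity_id[d$truth$entity_type == "chronic_patient"]
  is_chronic <- d$prescriptions$patient_id %in% chronic_pat
  binom_bounds <- function(p, n) p + c(-1, 1) * qnorm(0.995) * sqrt(p * (1 - p) / n)
  f5 <- mean(der$exceeds_day_threshold[!is_chronic])
  n5 <- sum(!is_chronic)
  expect_true(f5 > binom_bounds(0.2731, n5)[1] && f5 < binom_bounds(0.2731, n5)[2])
  f50 <- mean(der$exceeds_acute_medd[!is_chronic])
  expect_true(f50 > binom_bounds(0.1306, n5)[1] && f50 < binom_bounds(0.1306, n5)[2])
  f90 <- mean(der$exceeds_chronic_medd[is_chronic])
  n90 <- sum(is_chronic)
  expect_true(f90 > binom_bounds(0.0664, n90)[1] && f90 < binom_bounds(0.0664, n90)[2])
})

test_that("injected chronic patients satisfy the registry rule once established", {
  d <- simulate_prescribing_data(small_cfg())
  cfg <- default_run_config()
  der <- derive_prescriptions(d$prescriptions, d$drugs, cfg)
  as_of <- quarter_window(d$quarters[length(d$quarters)])$end_date - 1
  reg <- chronic_registry(d$prescriptions, der, as_of, cfg)
  injected <- d$truth$entity_id[d$truth$entity_type == "chronic_patient"]
  expect_gte(mean(injected %in% reg$chronic_patient_ids), 0.99)
  # and no acute, single-prescription patient lands on the registry
  acute <- setdiff(unique(d$prescriptions$patient_id), injected)
  expect_equal(intersect(acute, reg$chronic_patient_ids), character())
})

test_that("the worked fixture validates cleanly and covers every status", {
  dir <- withr::local_tempdir()
  fx <- generate_worked_fixture(out_dir = dir)
  expect_lte(nrow(fx$prescriptions), 50)
  rxs <- read_prescriptions(file.path(dir, "prescriptions.csv"),
                            read_drug_table(file.path(dir, "drugs.csv")))
  expect_equal(nrow(io_rejects(rxs)), 0)
  expect_equal(nrow(rxs), nrow(fx$prescriptions))
  pipe <- fixture_pipeline()
  expect_setequal(unique(pipe$flags$status), c("within", "outlier", "extreme_outlier"))
})
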