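#' The shipped oral-MME drug conversion table
#'
#' A versioned CSV fixture of common oral opioids (analgesics, antitussives,
#' and combination products) with published oral morphine-equivalent
#' conversion factors. Combination products carry the opioid component's
#' strength only. Methadone's dose-dependent conversion tiers are not
#' modelled (no methadone entry is shipped); transdermal and buccal forms are
#' out of scope.
#'
#' @return Drug table as from [read_drug_table()].
#' @export
default_drug_table <- function() {
  read_drug_table(system.file("extdata", "drugs.csv", package = "rxscorecard"))
}

#' Simulation configuration
#'
#' Defaults emulate a three-division health system with 68 specialties and
#' about 2,000 active prescribers: heavy-tailed per-provider prescribing rates
#' (log-normal rates with negative-binomial quarterly counts), a small
#' fraction of inflated outlier prescribers, guideline-exceedance fractions of
#' 27.31% (>5-day supply, nonchronic), 13.06% (>50 MEDD, nonchronic) and 6.64%
#' (>90 MEDD, chronic), a chronic-patient maintenance stream, and a
#' multiplicative quarterly volume trend of 0.984. A lead-in of unscored
#' history quarters gives the 12-month lookbacks real data to work on.
#'
#' @param ... Named overrides of any field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_divisions = 3,
    n_specialties = 68,
    providers_per_specialty = 30,
    inactive_fraction = 0.10,
    rate_meanlog = log(8),
    rate_sdlog = 0.6,
    specialty_sdlog = 0.3,
    nb_size = 12,
    outlier_fraction = 0.03,
    outlier_rate_multiplier = 5,
    frac_gt5day = 0.2731,
    frac_gt50medd = 0.1306,
    frac_gt90medd_chronic = 0.0664,
    chronic_rx_fraction = 0.15,
    trend_ratio = 0.984,
    n_quarters = 5,
    first_quarter = "2020Q3",
    history_quarters = 4,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort_fatal(sprintf("unknown sim_config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  for (f in c("outlier_fraction", "frac_gt5day", "frac_gt50medd",
              "frac_gt90medd_chronic", "chronic_rx_fraction", "inactive_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort_fatal(sprintf("%s must be in [0, 1]", f))
  }
  if (cfg$outlier_rate_multiplier < 1) abort_fatal("outlier_rate_multiplier must be >= 1")
  if (cfg$trend_ratio <= 0) abort_fatal("trend_ratio must be > 0")
  structure(cfg, class = "sim_config")
}

quarter_seq <- function(first_label, from, to) {
  m <- regmatches(first_label, regexec("^([0-9]{4})Q([1-4])$", first_label))[[1]]
  base <- as.integer(m[2]) * 4 + (as.integer(m[3]) - 1)
  idx <- base + seq(from, to)
  sprintf("%dQ%d", idx %/% 4, idx %% 4 + 1)
}

# (drug, units_per_dose, doses_per_day) combinations grouped by MEDD band
sig_combos <- function(drug_table) {
  grid <- expand.grid(i = seq_len(nrow(drug_table)), upd = 1:2, dpd = 1:4)
  combos <- tibble(
    drug_code = drug_table$drug_code[grid$i],
    units_per_dose = grid$upd,
    max_doses_per_day = grid$dpd,
    medd = drug_table$strength_mg_per_unit[grid$i] * grid$upd * grid$dpd *
      drug_table$mme_factor[grid$i]
  )
  list(
    le50 = combos %>% filter(medd <= 50, medd > 0),
    gt50 = combos %>% filter(medd > 50, medd <= 90),
    gt90 = combos %>% filter(medd > 90)
  )
}

#' Generate a synthetic multi-division prescription dataset
#'
#' Draws a provider population, per-provider prescribing rates, and
#' prescription-level records under the configured study conditions, together
#' with a ground-truth file labelling injected outlier providers and chronic
#' patients. Ground truth is the contract between generator and tests; the
#' pipeline never reads it. Output is byte-identical for a fixed seed.
#'
#' Nonchronic (acute) prescriptions follow the negative-binomial quarterly
#' counts with the configured trend; chronic patients instead receive a
#' deterministic 30-day maintenance prescription every 30 days (day supply 30,
#' one refill), which guarantees they satisfy the chronic-registry rule from
#' their third fill onward. Each acute prescription goes to a fresh patient.
#'
#' @param config A [sim_config()] list.
#' @param out_dir Optional directory; when given, writes `providers.csv`,
#'   `drugs.csv`, `prescriptions.csv`, `truth.csv`.
#' @return List of tibbles: `providers`, `drugs`, `prescriptions`, `truth`,
#'   plus `quarters` (scored quarter labels).
#' @export
simulate_prescribing_data <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  drugs <- default_drug_table()
  combos <- sig_combos(drugs)

  ## provider roster -----------------------------------------------------
  spc <- sprintf("SP%02d", seq_len(config$n_specialties))
  spc_division <- sprintf("D%d", (seq_len(config$n_specialties) - 1) %% config$n_divisions + 1)
  n_active <- config$n_specialties * config$providers_per_specialty
  n_inactive <- round(config$inactive_fraction * n_active)
  n_prov <- n_active + n_inactive
  spc_idx <- c(rep(seq_len(config$n_specialties), each = config$providers_per_specialty),
               sample(seq_len(config$n_specialties), n_inactive, replace = TRUE))
  providers <- tibble(
    provider_id = sprintf("P%05d", seq_len(n_prov)),
    name = sprintf("Provider %05d", seq_len(n_prov)),
    role = sample(PROVIDER_ROLES, n_prov, replace = TRUE,
                  prob = c(0.697, 0.163, 0.083, 0.055)),
    specialty = spc[spc_idx],
    division = spc_division[spc_idx]
  )
  active <- seq_len(n_active)

  ## per-provider rates --------------------------------------------------
  spc_shift <- rnorm(config$n_specialties, 0, config$specialty_sdlog)
  rate <- rlnorm(n_active, config$rate_meanlog + spc_shift[spc_idx[active]],
                 config$rate_sdlog)
  n_outlier <- round(config$outlier_fraction * n_active)
  outlier_idx <- sort(sample(active, n_outlier))
  # inflated prescribers sit at multiplier x their specialty's median rate
  # (never below their own draw), i.e. well into the right tail of their peers
  spc_median <- tapply(rate, spc_idx[active], stats::median)
  rate[outlier_idx] <- pmax(
    rate[outlier_idx],
    config$outlier_rate_multiplier * spc_median[as.character(spc_idx[outlier_idx])]
  )

  ## quarters ------------------------------------------------------------
  labels <- quarter_seq(config$first_quarter, -config$history_quarters,
                        config$n_quarters - 1)
  qidx <- seq(-config$history_quarters, config$n_quarters - 1)
  years <- unique(as.integer(substr(labels, 1, 4)))
  windows <- quarter_windows(years)
  windows <- windows[match(labels, windows$label), ]
  horizon_start <- windows$start_date[1]
  horizon_end <- windows$end_date[nrow(windows)]

  ## acute prescriptions: NB counts around the trended rate ---------------
  nq <- length(labels)
  mu <- outer(rate, pmax(qidx, 0), function(r, q) r * config$trend_ratio^q)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_size), nrow = n_active)
  total <- sum(counts)
  prov_rep <- rep(rep(providers$provider_id[active], nq), as.vector(counts))
  q_rep <- rep(rep(seq_len(nq), each = n_active), as.vector(counts))
  dates <- windows$start_date[q_rep] +
    floor(runif(total) * as.integer(windows$end_date[q_rep] - windows$start_date[q_rep]))

  day_exceed <- runif(total) < config$frac_gt5day
  medd_exceed <- runif(total) < config$frac_gt50medd
  pick <- function(pool, n) pool[sample.int(nrow(pool), n, replace = TRUE), ]
  acute <- tibble(prescriber_id = prov_rep, written_date = dates)
  lo <- pick(combos$le50, sum(!medd_exceed))
  hi <- pick(combos$gt50, sum(medd_exceed))
  combo <- tibble(drug_code = character(total), units_per_dose = numeric(total),
                  max_doses_per_day = numeric(total))
  combo[!medd_exceed, ] <- lo[, c("drug_code", "units_per_dose", "max_doses_per_day")]
  combo[medd_exceed, ] <- hi[, c("drug_code", "units_per_dose", "max_doses_per_day")]
  daily <- combo$units_per_dose * combo$max_doses_per_day
  qty <- integer(total)
  n_lo <- sum(!day_exceed)
  qty[!day_exceed] <- 1 + floor(runif(n_lo) * (5 * daily[!day_exceed]))
  qty[day_exceed] <- 5 * daily[day_exceed] + 1 +
    floor(runif(total - n_lo) * (9 * daily[day_exceed]))
  acute <- dplyr::bind_cols(acute, combo) %>%
    mutate(
      quantity_dispensed = qty,
      refills = sample(0:2, total, replace = TRUE, prob = c(0.85, 0.12, 0.03)),
      patient_id = sprintf("PT%07d", seq_len(total)),
      authorizing_id = NA_character_
    )

  ## chronic maintenance streams ------------------------------------------
  pool_n <- rpois(n_active, config$chronic_rx_fraction /
                    (1 - config$chronic_rx_fraction) * rate / 3)
  chronic_owner <- rep(providers$provider_id[active], pool_n)
  n_chronic <- length(chronic_owner)
  chronic_rx <- NULL
  if (n_chronic > 0) {
    chronic_pid <- sprintf("CH%05d", seq_len(n_chronic))
    offset <- sample(0:29, n_chronic, replace = TRUE)
    n_fills <- as.integer((as.integer(horizon_end - horizon_start) - offset - 1) %/% 30 + 1)
    fill_i <- sequence(n_fills) - 1
    owner_rep <- rep(chronic_owner, n_fills)
    pid_rep <- rep(chronic_pid, n_fills)
    fill_dates <- horizon_start + rep(offset, n_fills) + 30 * fill_i
    nfill <- length(fill_dates)
    hi90 <- runif(nfill) < config$frac_gt90medd_chronic
    c_lo <- pick(dplyr::bind_rows(combos$le50, combos$gt50), sum(!hi90))
    c_hi <- pick(combos$gt90, sum(hi90))
    ccombo <- tibble(drug_code = character(nfill), units_per_dose = numeric(nfill),
                     max_doses_per_day = numeric(nfill))
    ccombo[!hi90, ] <- c_lo[, c("drug_code", "units_per_dose", "max_doses_per_day")]
    ccombo[hi90, ] <- c_hi[, c("drug_code", "units_per_dose", "max_doses_per_day")]
    chronic_rx <- tibble(prescriber_id = owner_rep, written_date = fill_dates) %>%
      dplyr::bind_cols(ccombo) %>%
      mutate(
        quantity_dispensed = 30 * units_per_dose * max_doses_per_day,
        refills = 1L,
        patient_id = pid_rep,
        authorizing_id = NA_character_
      )
  }

  rxs <- bind_rows(acute, chronic_rx) %>%
    arrange(written_date, prescriber_id, patient_id) %>%
    mutate(rx_id = sprintf("RX%08d", row_number())) %>%
    select(rx_id, patient_id, prescriber_id, authorizing_id, drug_code,
           units_per_dose, max_doses_per_day, quantity_dispensed, refills,
           written_date)

  truth <- bind_rows(
    tibble(entity_type = "outlier_provider",
           entity_id = providers$provider_id[outlier_idx],
           label = "injected_outlier"),
    if (n_chronic > 0) tibble(entity_type = "chronic_patient",
                              entity_id = sprintf("CH%05d", seq_len(n_chronic)),
                              label = "chronic")
  )

  out <- list(providers = providers, drugs = drugs, prescriptions = rxs,
              truth = truth, quarters = labels[qidx >= 0])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records_csv(providers, file.path(out_dir, "providers.csv"))
    write_records_csv(drugs, file.path(out_dir, "drugs.csv"))
    write_records_csv(rxs, file.path(out_dir, "prescriptions.csv"))
    write_records_csv(truth, file.path(out_dir, "truth.csv"))
  }
  out
}
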