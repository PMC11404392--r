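cfg <- default_run_config()

test_that("quartiles follow the pinned linear-interpolation definition", {
  expect_equal(quartiles(c(5, 5, 5, 5)), c(q1 = 5, median = 5, q3 = 5))
  expect_equal(quartiles(c(1, 2, 3, 4, 5)), c(q1 = 2, median = 3, q3 = 4))
  expect_equal(quartiles(7), c(q1 = 7, median = 7, q3 = 7))
  expect_error(quartiles(numeric()), "empty")
  set.seed(3)
  for (n in c(2, 3, 7, 20, 51)) {
    v <- round(rlnorm(n, 2, 1))
    q <- quartiles(v)
    expect_equal(unname(q),
                 c(oracle_quantile(v, 0.25), oracle_quantile(v, 0.5), oracle_quantile(v, 0.75)))
  }
})

mk_metrics <- function(values, specialty = "GEN", division = "D1") {
  tibble::tibble(
    provider_id = sprintf("P%02d", seq_along(values)), quarter = "2021Q3",
    division = division, specialty = specialty,
    m1_rx_count = values, m2_patient_count = 0L, m3_gt5day = 0L,
    m4_gt50medd = 0L, m5_gt90medd = 0L
  )
}

test_that("threshold modes match hand computation, including the zero-IQR group", {
  m <- mk_metrics(c(0, 0, 1, 2, 10))
  th <- compute_thresholds(m, cfg)
  row <- th[th$metric == "m1_rx_count", ]
  expect_equal(row$outlier_threshold, 1.5 * (oracle_quantile(c(0, 0, 1, 2, 10), .75) -
                                             oracle_quantile(c(0, 0, 1, 2, 10), .25)))
  expect_equal(row$extreme_threshold, 3 * row$outlier_threshold)

  tk <- compute_thresholds(mk_metrics(1:5), default_run_config(threshold_mode = "tukey_fence"))
  expect_equal(tk$outlier_threshold[tk$metric == "m1_rx_count"], 7)  # 4 + 1.5*2

  same <- mk_metrics(c(3, 3, 3, 4, 4))
  th0 <- compute_thresholds(same, cfg)
  expect_equal(th0$outlier_threshold[th0$metric == "m1_rx_count"], 1.5) # q3-q1 = 1 here
  # identical providers: IQR 0, so both thresholds collapse to 0 and anything
  # strictly above the common value is an extreme outlier
  allsame <- compute_thresholds(mk_metrics(c(3, 3, 3, 3)), cfg)
  expect_equal(allsame$iqr[allsame$metric == "m1_rx_count"], 0)
  mz <- mk_metrics(c(0, 0, 0, 0, 5))
  flz <- flag_providers(mz, compute_thresholds(mz, cfg))
  m1z <- flz[flz$metric == "m1_rx_count", ]
  expect_equal(m1z$status[m1z$value == 5], "extreme_outlier")
  expect_equal(unique(m1z$status[m1z$value == 0]), "within")
})

test_that("small groups are flagged low-n but still get thresholds", {
  th <- compute_thresholds(mk_metrics(c(1, 2, 3)), cfg)   # min_group_size 5
  expect_true(all(th$low_n_flag))
  expect_true(all(is.finite(th$outlier_threshold)))
  th2 <- compute_thresholds(mk_metrics(1:8), cfg)
  expect_false(any(th2$low_n_flag))
})

test_that("status uses strict comparisons and extreme implies outlier", {
  m <- mk_metrics(c(0, 1, 2, 3, 6, 19))   # q1=1.25 q3=5.25... just use computed thresholds
  th <- compute_thresholds(m, cfg)
  fl <- flag_providers(m, th)
  m1 <- fl[fl$metric == "m1_rx_count", ]
  thr <- th$outlier_threshold[th$metric == "m1_rx_count"]
  ext <- th$extreme_threshold[th$metric == "m1_rx_count"]
  for (i in seq_len(nrow(m1))) {
    expect_equal(m1$status[i], oracle_status(m1$value[i], c(outlier = thr, extreme = ext)))
  }
  # boundary: value exactly at threshold is within
  mb <- mk_metrics(c(0, 0, 2, 2, 3))      # iqr 2, thr 3 -> the 3 is within
  flb <- flag_providers(mb, compute_thresholds(mb, cfg))
  expect_equal(flb$status[flb$metric == "m1_rx_count" & flb$value == 3], "within")
  expect_error(flag_providers(mk_metrics(1:3, specialty = "OTHER"), th), "no thresholds")
})

test_that("flags agree with a sort-based oracle and are permutation invariant", {
  set.seed(19)
  for (rep in 1:50) {
    values <- rpois(sample(3:50, 1), lambda = sample(c(2, 8, 20), 1))
    m <- mk_metrics(values)
    th <- compute_thresholds(m, cfg)
    fl <- flag_providers(m, th)
    thr <- oracle_thresholds(values)
    m1 <- fl[fl$metric == "m1_rx_count", ]
    expect_equal(m1$status, vapply(m1$value, oracle_status, "", thr = thr))
    # permutation invariance
    perm <- sample(nrow(m))
    fl2 <- flag_providers(m[perm, ], compute_thresholds(m[perm, ], cfg))
    joined <- merge(as.data.frame(fl), as.data.frame(fl2),
                    by = c("provider_id", "metric"))
    expect_true(all(joined$status.x == joined$status.y))
  }
})

test_that("raising a provider's value never turns an outlier into within", {
  set.seed(23)
  values <- rpois(20, 6)
  m <- mk_metrics(values)
  fl <- flag_providers(m, compute_thresholds(m, cfg))
  m1 <- fl[fl$metric == "m1_rx_count", ]
  rank_of <- function(s) match(s, c("within", "outlier", "extreme_outlier"))
  for (i in c(1, 5, 12)) {
    m2 <- m
    m2$m1_rx_count[i] <- m2$m1_rx_count[i] + 10L
    fl2 <- flag_providers(m2, compute_thresholds(m, cfg))  # same thresholds
    m1b <- fl2[fl2$metric == "m1_rx_count", ]
    expect_gte(rank_of(m1b$status[i]), rank_of(m1$status[i]))
  }
})
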