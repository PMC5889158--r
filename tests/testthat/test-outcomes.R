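test_that("currency conversion rounds half-up to whole dollars", {
  expect_equal(convert_currency(0), 0)
  expect_equal(convert_currency(445314), 14695)
  expect_equal(convert_currency(404950), 13363)
  expect_equal(convert_currency(100, rate = 0.005), 1) # 0.5 rounds up
  expect_equal(convert_currency(1000, digits = NULL), 33)
  expect_error(convert_currency(-1), class = "claimsir_config_error")
  expect_error(convert_currency(10, rate = 0), class = "claimsir_config_error")
})

test_that("a single admission contributes its day count and costs to year 1", {
  bundle <- one_patient_bundle(
    extra_ph = ph_row(date = IDX + 20, days = 335L, cost = 300000),
    extra_mc = dplyr::bind_rows(
      mc_row(
        setting = "inpatient", start = IDX + 100, end = IDX + 103,
        med = 0, nonmed = 20000
      ),
      mc_row(start = IDX + 30, med = 500, nonmed = 900),
      mc_row(setting = "ED", start = IDX + 60, nonmed = 1500)
    )
  )
  cohort <- one_patient_cohort()
  results <- classify_response(cohort, bundle)
  s <- summarize_year(cohort, results, bundle, year = 1)
  all_row <- s[s$cohort == "all", ]
  expect_equal(all_row$n, 1)
  expect_equal(all_row$admissions_mean, 1)
  expect_equal(all_row$hospital_days_mean, 3)
  expect_equal(all_row$ed_visits_mean, 1)
  expect_equal(all_row$outpatient_visits_mean, 1)
  expect_equal(all_row$inpatient_ntd_mean, 20000)
  expect_equal(all_row$outpatient_ntd_mean, 900)
  expect_equal(all_row$ed_ntd_mean, 1500)
  # medication: pharmacy costs plus medication lines on medical claims
  expect_equal(all_row$medication_ntd_mean, 300000 + 500)
  expect_equal(
    all_row$total_ntd_mean,
    all_row$inpatient_ntd_mean + all_row$outpatient_ntd_mean +
      all_row$ed_ntd_mean + all_row$medication_ntd_mean
  )
  expect_equal(all_row$total_usd_mean, all_row$total_ntd_mean * 0.033)
  expect_error(summarize_year(cohort, results, bundle, year = 4),
    class = "claimsir_config_error"
  )
})

test_that("same-day admissions count one hospital day", {
  bundle <- one_patient_bundle(
    extra_mc = mc_row(setting = "inpatient", start = IDX + 10, end = IDX + 10)
  )
  cohort <- one_patient_cohort()
  results <- classify_response(cohort, bundle)
  s <- summarize_year(cohort, results, bundle, year = 1)
  expect_equal(s$hospital_days_mean[s$cohort == "all"], 1)
})

test_that("cost totals are conserved per summary row and per patient", {
  run <- preset_run()
  h <- run$report$hcru_costs
  expect_equal(
    h$total_ntd_mean,
    h$inpatient_ntd_mean + h$outpatient_ntd_mean + h$ed_ntd_mean + h$medication_ntd_mean
  )
  per <- claimsir:::patient_year_quantities(run$cohort, run$bundle, 1)
  expect_equal(
    per$total_ntd,
    per$inpatient_ntd + per$outpatient_ntd + per$ed_ntd + per$medication_ntd
  )
  # year-over-year n is monotone non-increasing within each cohort
  for (g in unique(h$cohort)) {
    expect_true(all(diff(h$n[h$cohort == g]) <= 0))
  }
})

test_that("time to switch is the conditional mean over switchers", {
  sw <- tibble::tibble(
    patient_id = "P1", from_agent = "adalimumab",
    to_agent = "etanercept", switch_day = 100
  )
  out <- time_to_switch(sw)
  expect_equal(out$mean_days, 100)
  expect_equal(out$n, 1L)
  # agents without switchers are absent, not zero
  expect_false("etanercept" %in% out$from_agent)
  expect_equal(nrow(time_to_switch(sw[0, ])), 0)
  # brute-force mean on a random fixture
  set.seed(40)
  sw2 <- tibble::tibble(
    patient_id = sprintf("Q%02d", 1:30),
    from_agent = sample(c("adalimumab", "etanercept"), 30, replace = TRUE),
    to_agent = "tocilizumab",
    switch_day = sample(100:1000, 30)
  )
  out <- time_to_switch(sw2)
  for (ag in unique(sw2$from_agent)) {
    days <- sw2$switch_day[sw2$from_agent == ag]
    expect_equal(out$mean_days[out$from_agent == ag], sum(days) / length(days))
  }
})

test_that("switch matrix reproduces published row percentages from counts", {
  counts <- c(etanercept = 32, tocilizumab = 31, golimumab = 9, abatacept = 7)
  sw <- tibble::tibble(
    patient_id = sprintf("R%02d", seq_len(sum(counts))),
    from_agent = "adalimumab",
    to_agent = rep(names(counts), counts),
    switch_day = 500
  )
  m <- switch_matrix(sw)
  expect_equal(m$n, unname(counts[m$to_agent]))
  expect_equal(
    stats::setNames(m$pct, m$to_agent),
    c(etanercept = 41, tocilizumab = 39, golimumab = 11, abatacept = 9)
  )
  expect_equal(sum(m$pct), 100)
  expect_equal(nrow(switch_matrix(sw[0, ])), 0)
  # half-up rounding drifts a k-destination row sum by at most k/2 points
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    sw2 <- tibble::tibble(
      patient_id = as.character(seq_len(40)),
      from_agent = "etanercept",
      to_agent = sample(paste0("agent", 1:k), 40, replace = TRUE),
      switch_day = 1
    )
    expect_lte(abs(sum(switch_matrix(sw2)$pct) - 100), k / 2)
  }
})

test_that("derived report cells are computed from their components", {
  run <- preset_run()
  h <- run$report$hcru_costs
  d <- run$report$derived
  for (i in seq_len(nrow(d))) {
    row <- h[h$cohort == d$cohort[i] & h$year == d$year[i], ]
    expect_equal(
      d$nonmedication_usd_mean[i],
      convert_currency(row$inpatient_ntd_mean + row$outpatient_ntd_mean + row$ed_ntd_mean)
    )
    expect_equal(
      d$medication_share_pct[i],
      round_half_up(100 * row$medication_ntd_mean / row$total_ntd_mean)
    )
  }
})

test_that("an empty cohort yields empty, not failing, outputs", {
  b <- claims_bundle()
  cohort <- one_patient_cohort()[0, ]
  res <- classify_response(cohort, b)
  expect_equal(nrow(res), 0)
  att <- attribute_criteria(res)
  expect_equal(att$pct_marginal, rep(0, 5))
  expect_equal(nrow(extract_switches(cohort, b)), 0)
})
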