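# Independent claim scanner: re-derives the five criterion flags for one
# patient directly from raw claims with day-by-day logic, sharing no code
# with the classifier.
scan_flags <- function(bundle, pid, index_date, index_agent, w_end,
                       config = study_config()) {
  ph <- bundle$pharmacy_claims[bundle$pharmacy_claims$patient_id == pid, ]
  mc <- bundle$medical_claims[bundle$medical_claims$patient_id == pid, ]
  day <- as.numeric(ph$dispense_date - index_date)
  mday <- as.numeric(mc$start_date - index_date)

  own <- ph$drug_class == "bDMARD" & ph$bdmard_agent %in% index_agent
  covered <- logical(365)
  for (i in which(own)) {
    dd <- seq(day[i], day[i] + ph$days_supplied[i] - 1)
    dd <- dd[dd >= 0 & dd < w_end]
    covered[dd + 1] <- TRUE
  }
  low <- sum(covered) + (365 - w_end) < ceiling(0.8 * 365)

  other <- ph$drug_class == "bDMARD" & !(ph$bdmard_agent %in% index_agent)
  switch_add <- any(other & day >= 0 & day < w_end)

  cs <- ph$drug_class == "csDMARD"
  new_cs <- FALSE
  for (cmp in unique(ph$drug_code[cs])) {
    rows <- cs & ph$drug_code == cmp
    if (any(rows & day >= 1 & day < w_end) && !any(rows & day >= -365 & day <= 0)) {
      new_cs <- TRUE
    }
  }

  inj <- sum(mc$is_gc_joint_injection & mday >= 0 & mday < w_end) >= 2

  gc <- ph$drug_class == "oral_GC"
  pre <- sum(ph$prednisone_equivalent_mg_total[gc & day >= -365 & day < 0]) / 365
  in_cmp <- gc & day >= 90 & day < w_end
  gc_up <- if (w_end > 90 && any(in_cmp)) {
    sum(ph$prednisone_equivalent_mg_total[in_cmp]) / (w_end - 90) > pre
  } else {
    FALSE
  }
  c(
    low_adherence = low, switch_or_add = switch_add, new_csdmard = new_cs,
    gc_injections = inj, oral_gc_increase = gc_up
  )
}

test_that("generation is deterministic under a fixed seed", {
  spec <- small_scenario(n = 60L, seed = 9L, n_decoys = 5L)
  g1 <- generate_claims(spec)
  g2 <- generate_claims(spec)
  for (nm in names(g1$bundle)) {
    expect_identical(as.data.frame(g1$bundle[[nm]]), as.data.frame(g2$bundle[[nm]]))
  }
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
  g3 <- generate_claims(small_scenario(n = 60L, seed = 10L, n_decoys = 5L))
  expect_false(identical(
    as.data.frame(g1$bundle$pharmacy_claims),
    as.data.frame(g3$bundle$pharmacy_claims)
  ))
})

test_that("an all-stable scenario classifies every patient as stable", {
  spec <- small_scenario(
    n = 10L, seed = 2L,
    status_proportions = c(stable = 1, IR = 0, unknown = 0)
  )
  gen <- generate_claims(spec)
  built <- build_cohort(gen$bundle)
  expect_equal(nrow(built$cohort), 10)
  res <- classify_response(built$cohort, gen$bundle)
  expect_equal(unique(res$status), "Stable")
})

test_that("infeasible scenario specifications are rejected", {
  expect_error(
    scenario_spec(
      n_patients = 50,
      criterion_marginals = c(
        low_adherence = 0, switch_or_add = 0, new_csdmard = 0,
        gc_injections = 0, oral_gc_increase = 0
      )
    ),
    class = "claimsir_spec_error"
  )
  expect_error(
    scenario_spec(n_patients = 50, status_proportions = c(stable = 0.6, IR = 0.6, unknown = -0.2)),
    class = "claimsir_spec_error"
  )
})

test_that("planted flags are realized in the emitted claims (scanner oracle)", {
  gen <- generate_claims(small_scenario(n = 200L, seed = 11L))
  tr <- gen$truth
  flags <- c(
    "low_adherence", "switch_or_add", "new_csdmard",
    "gc_injections", "oral_gc_increase"
  )
  for (i in seq_len(nrow(tr))) {
    w_end <- if (is.na(tr$censor_day[i])) 365 else tr$censor_day[i]
    rec <- scan_flags(gen$bundle, tr$patient_id[i], tr$index_date[i],
      tr$index_agent[i], w_end)
    expect_equal(unname(rec), unname(unlist(tr[i, flags])),
      info = paste("patient", tr$patient_id[i])
    )
  }
  # planted counts equal the scenario's exact per-criterion counts
  n_ir <- sum(tr$status == "IR")
  expected <- round(gen$spec$criterion_marginals * n_ir)
  expect_equal(unname(colSums(as.matrix(tr[flags]))), unname(expected))
})

test_that("classifier recovers planted labels exactly on a non-preset scenario", {
  gen <- generate_claims(small_scenario(n = 200L, seed = 11L))
  built <- build_cohort(gen$bundle)
  res <- classify_response(built$cohort, gen$bundle)
  m <- dplyr::inner_join(gen$truth, res, by = "patient_id", suffix = c(".t", ".r"))
  expect_equal(nrow(m), 200)
  expect_identical(m$status.r, m$status.t)
  for (f in c("low_adherence", "switch_or_add", "new_csdmard", "gc_injections", "oral_gc_increase")) {
    expect_identical(m[[paste0(f, ".r")]], m[[paste0(f, ".t")]])
  }
})

test_that("realized criterion frequencies track the marginals at large n", {
  spec <- small_scenario(n = 600L, seed = 21L)
  gen <- generate_claims(spec)
  ir <- gen$truth[gen$truth$status == "IR", ]
  for (f in names(spec$criterion_marginals)) {
    p <- spec$criterion_marginals[[f]]
    se <- sqrt(p * (1 - p) / nrow(ir))
    expect_lt(abs(mean(ir[[f]]) - p), max(3 * se, 1.5 / nrow(ir)))
  }
})

test_that("nuisance claims never alter classification or ground truth", {
  gen <- generate_claims(small_scenario(n = 120L, seed = 5L))
  expect_identical(add_nuisance_claims(gen$bundle, 0), gen$bundle)
  noisy <- add_nuisance_claims(gen$bundle, intensity = 5, rng_seed = 99L)
  expect_gt(nrow(noisy$medical_claims), nrow(gen$bundle$medical_claims))
  built0 <- build_cohort(gen$bundle)
  built1 <- build_cohort(noisy)
  expect_identical(built1$cohort$patient_id, built0$cohort$patient_id)
  res0 <- classify_response(built0$cohort, gen$bundle)
  res1 <- classify_response(built1$cohort, noisy)
  expect_identical(res1$status, res0$status)
  expect_identical(res1$low_adherence, res0$low_adherence)
  # baseline comorbidity is untouched as well
  expect_identical(
    cohort_cci(built1$cohort, noisy)$cci,
    cohort_cci(built0$cohort, gen$bundle)$cci
  )
})

test_that("nuisance intensity raises outpatient visit counts by about its mean", {
  gen <- generate_claims(small_scenario(n = 1000L, seed = 31L))
  intensity <- 4
  noisy <- add_nuisance_claims(gen$bundle, intensity, rng_seed = 7L)
  added <- nrow(noisy$medical_claims) - nrow(gen$bundle$medical_claims)
  n <- nrow(gen$bundle$enrollment)
  spans <- pmin(3 * 365, as.numeric(gen$bundle$enrollment$coverage_end -
    gen$bundle$enrollment$coverage_start) + 1) / 365
  lambda <- intensity * sum(spans)
  expect_lt(abs(added - lambda), 3 * sqrt(lambda))
})
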