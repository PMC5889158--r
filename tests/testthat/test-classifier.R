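test_that("PDC matches hand-computed interval unions and the strict threshold", {
  # full-year supply
  expect_equal(compute_pdc(IDX, 365L, IDX), 1.0)
  # exactly 292 covered days is PDC 0.8, which is NOT low adherence
  expect_equal(compute_pdc(IDX, 292L, IDX), 292 / 365)
  bundle <- one_patient_bundle(extra_ph = ph_row(date = IDX, days = 292L))
  res <- classify_response(one_patient_cohort(), bundle)
  expect_false(res$low_adherence)
  expect_equal(res$status, "Stable")
  # one fewer covered day crosses the strict boundary
  b291 <- claims_bundle(
    enrollment = enroll_row(), catastrophic_illness = ci_row(),
    medical_claims = mc_row(start = "2009-08-01"),
    pharmacy_claims = ph_row(date = IDX, days = 291L)
  )
  res <- classify_response(one_patient_cohort(), b291)
  expect_true(res$low_adherence)
  expect_equal(res$status, "IR")
  # overlapping 30-day dispenses at day 0 and day 15 cover 45 distinct days
  expect_equal(
    compute_pdc(IDX + c(0, 15), c(30L, 30L), IDX),
    45 / 365
  )
  expect_error(compute_pdc(IDX, 0L, IDX), class = "claimsir_invariant_error")
})

test_that("interval-union PDC equals brute-force day enumeration (property)", {
  set.seed(20)
  for (i in 1:300) {
    m <- sample(1:15, 1)
    day <- sample(-30:400, m, replace = TRUE)
    supply <- sample(1:120, m, replace = TRUE)
    expect_equal(
      compute_pdc(IDX + day, supply, IDX),
      brute_pdc(day, supply),
      info = paste("case", i)
    )
  }
})

test_that("PDC agrees with an interval-library union on random dispense sets", {
  set.seed(21)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    day <- sample(0:360, m, replace = TRUE)
    supply <- sample(1:90, m, replace = TRUE)
    ir <- IRanges::restrict(
      IRanges::reduce(IRanges::IRanges(start = day + 1, width = supply)),
      start = 1, end = 365
    )
    expect_equal(compute_pdc(IDX + day, supply, IDX), sum(IRanges::width(ir)) / 365)
  }
})

test_that("splitting a dispense into contiguous parts leaves PDC unchanged", {
  set.seed(22)
  for (i in 1:100) {
    day <- sample(0:300, 3)
    supply <- sample(10:60, 3, replace = TRUE)
    whole <- compute_pdc(IDX + day, supply, IDX)
    cut <- sample(seq_len(supply[1] - 1), 1)
    split_days <- c(day[1], day[1] + cut, day[-1])
    split_supply <- c(cut, supply[1] - cut, supply[-1])
    expect_equal(compute_pdc(IDX + split_days, split_supply, IDX), whole)
  }
})

test_that("switch-or-add respects the half-open follow-up window", {
  ph <- function(day) ph_row(date = IDX + day, code = "B-TOC", agent = "tocilizumab")
  base <- ph_row(date = IDX)
  expect_false(detect_switch_or_add(base, "etanercept", IDX)$flag)
  hit <- detect_switch_or_add(dplyr::bind_rows(base, ph(200)), "etanercept", IDX)
  expect_true(hit$flag)
  expect_equal(hit$first_date, IDX + 200)
  # the day after the window closes does not count
  expect_false(detect_switch_or_add(dplyr::bind_rows(base, ph(365)), "etanercept", IDX)$flag)
  expect_true(detect_switch_or_add(dplyr::bind_rows(base, ph(364)), "etanercept", IDX)$flag)
})

test_that("a csDMARD is new only without pre-index or index-day use", {
  mtx <- function(day) ph_row(date = IDX + day, code = "MTX", class = "csDMARD", agent = NA)
  lef <- function(day) ph_row(date = IDX + day, code = "LEF", class = "csDMARD", agent = NA)
  # continuing methotrexate is not new
  expect_false(detect_new_csdmard(dplyr::bind_rows(mtx(-100), mtx(50)), IDX)$flag)
  # first-ever leflunomide at day 100 is
  out <- detect_new_csdmard(dplyr::bind_rows(mtx(-100), mtx(50), lef(100)), IDX)
  expect_true(out$flag)
  expect_equal(out$first_date, IDX + 100)
  # dispensed on the index date itself -> not "after index"
  expect_false(detect_new_csdmard(lef(0), IDX)$flag)
  expect_true(detect_new_csdmard(lef(1), IDX)$flag)
})

test_that("glucocorticoid injections flag at the configured count", {
  inj <- function(day) mc_row(start = IDX + day, inj = TRUE)
  none <- count_gc_injections(mc_row(start = IDX + 5), IDX)
  expect_equal(none$count, 0)
  expect_false(none$flag)
  one <- count_gc_injections(inj(30), IDX)
  expect_false(one$flag)
  expect_true(count_gc_injections(inj(30), IDX, min_count = 1L)$flag)
  two <- count_gc_injections(dplyr::bind_rows(inj(200), inj(30)), IDX)
  expect_true(two$flag)
  expect_equal(two$count, 2)
  expect_equal(two$first_date, IDX + 200) # date the criterion is met
})

test_that("oral glucocorticoid increase uses prednisone equivalents and bridging", {
  gc <- function(day, mg) {
    ph_row(date = IDX + day, code = "PRED", class = "oral_GC", agent = NA, mg = mg)
  }
  cfg <- study_config()
  # flat 5 mg/day in both windows: no increase
  flat <- dplyr::bind_rows(gc(-300, 5 * 365), gc(120, 5 * 275))
  expect_false(detect_oral_gc_increase(flat, IDX, cfg)$flag)
  # new use over a steroid-free baseline counts
  newuse <- gc(150, 2 * 275)
  out <- detect_oral_gc_increase(newuse, IDX, cfg)
  expect_true(out$flag)
  expect_equal(out$pre_mean, 0)
  # dispenses inside the 90-day bridging window are ignored
  bridge_only <- gc(10, 3000)
  expect_false(detect_oral_gc_increase(bridge_only, IDX, cfg)$flag)
  # prednisolone 5 mg x 100 tablets pre-index vs methylprednisolone
  # 4 mg x 150 tablets in the comparison window (750 mg prednisone equivalents)
  expect_equal(prednisone_equivalents("MPRED", 4 * 150), 750)
  hand <- dplyr::bind_rows(
    gc(-200, prednisone_equivalents("PREDL", 5 * 100)),
    gc(150, prednisone_equivalents("MPRED", 4 * 150))
  )
  out <- detect_oral_gc_increase(hand, IDX, cfg)
  expect_equal(out$pre_mean, 500 / 365)
  expect_equal(out$follow_mean, 750 / 275)
  expect_true(out$flag)
})

test_that("classification handles censoring and assigns status by the decision rule", {
  # full-year enrollment, no criteria -> Stable
  res <- classify_response(one_patient_cohort(), one_patient_bundle(
    extra_ph = ph_row(date = IDX + 30, days = 335L)
  ))
  expect_equal(res$status, "Stable")
  expect_true(is.na(res$censor_day))
  # coverage ends at follow-up day 200 with no criteria -> Unknown
  # (drug supplied until the censor day, so adherence is not yet decidable)
  cens <- one_patient_bundle(
    enrollment = enroll_row(end = as.character(IDX + 199)),
    extra_ph = ph_row(date = IDX + 30, days = 170L)
  )
  res <- classify_response(one_patient_cohort(), cens)
  expect_equal(res$status, "Unknown")
  expect_equal(res$censor_day, 200L)
  # a criterion met before the censor day outranks Unknown
  cens_ir <- one_patient_bundle(
    enrollment = enroll_row(end = as.character(IDX + 199)),
    extra_ph = ph_row(date = IDX + 100, code = "B-TOC", agent = "tocilizumab")
  )
  res <- classify_response(one_patient_cohort(), cens_ir)
  expect_equal(res$status, "IR")
  expect_true(res$switch_or_add)
  # death censors the same way
  dead <- one_patient_bundle(
    enrollment = enroll_row(death = as.character(IDX + 99))
  )
  res <- classify_response(one_patient_cohort(), dead)
  expect_equal(res$status, "Unknown")
  expect_equal(res$censor_day, 100L)
  # a patient missing from enrollment is an error
  b <- one_patient_bundle()
  bad_cohort <- one_patient_cohort()
  bad_cohort$patient_id <- "P9"
  expect_error(classify_response(bad_cohort, b), class = "claimsir_invariant_error")
})

test_that("adding criterion events never moves a patient toward Stable", {
  gen <- generate_claims(small_scenario(n = 60L, seed = 17L))
  built <- build_cohort(gen$bundle)
  res0 <- classify_response(built$cohort, gen$bundle)
  extra <- dplyr::bind_rows(lapply(seq_len(nrow(built$cohort)), function(i) {
    mc_row(
      id = built$cohort$patient_id[i],
      start = built$cohort$index_date[i] + 40, inj = TRUE
    )
  }))
  extra2 <- extra
  extra2$start_date <- extra2$start_date + 17
  extra2$end_date <- extra2$start_date
  noisy <- claims_bundle(
    enrollment = gen$bundle$enrollment,
    catastrophic_illness = gen$bundle$catastrophic_illness,
    medical_claims = dplyr::bind_rows(gen$bundle$medical_claims, extra, extra2),
    pharmacy_claims = gen$bundle$pharmacy_claims
  )
  res1 <- classify_response(built$cohort, noisy)
  expect_false(any(res0$status == "IR" & res1$status != "IR"))
  # two added injections flag criterion 4 for everyone not censored early
  expect_true(all(res1$gc_injections | res1$status == "Unknown"))
})

test_that("criterion attribution separates marginals from first-met shares", {
  gen <- generate_claims(small_scenario(
    n = 10L, seed = 2L,
    status_proportions = c(stable = 1, IR = 0, unknown = 0)
  ))
  built <- build_cohort(gen$bundle)
  res <- classify_response(built$cohort, gen$bundle)
  att <- attribute_criteria(res)
  expect_equal(att$pct_marginal, rep(0, 5))
  expect_equal(att$pct_first_met, rep(0, 5))
  # one patient with two criteria: counted under both marginals, once first-met
  b <- one_patient_bundle(
    extra_ph = dplyr::bind_rows(
      ph_row(date = IDX + 30, days = 335L), # full adherence
      ph_row(date = IDX + 50, code = "B-TOC", agent = "tocilizumab")
    ),
    extra_mc = dplyr::bind_rows(
      mc_row(start = IDX + 10, inj = TRUE),
      mc_row(start = IDX + 20, inj = TRUE)
    )
  )
  res <- classify_response(one_patient_cohort(), b)
  att <- attribute_criteria(res)
  expect_equal(sum(att$n_marginal), 2)
  expect_equal(sum(att$n_first_met), 1)
  # injections completed on day 20, before the day-50 switch
  expect_equal(att$n_first_met[att$criterion == "gc_injections"], 1)
})
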