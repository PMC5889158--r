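# Hand-built single-row table constructors for small fixtures. All dates are
# ISO strings for readability; day offsets are relative to a 2010-04-01 index
# unless a test says otherwise.

IDX <- as.Date("2010-04-01")

enroll_row <- function(id = "P1", start = "2009-01-01", end = "2013-12-31",
                       birth = "1960-05-10", sex = "female", death = NA) {
  tibble::tibble(
    patient_id = id, birth_date = as.Date(birth), sex = sex,
    coverage_start = as.Date(start), coverage_end = as.Date(end),
    death_date = as.Date(death)
  )
}

ph_row <- function(id = "P1", date = IDX, code = "B-ETA", class = "bDMARD",
                   agent = "etanercept", days = 30L, mg = NA_real_, cost = 0) {
  tibble::tibble(
    patient_id = id, dispense_date = as.Date(date), drug_code = code,
    drug_class = class, bdmard_agent = agent, days_supplied = as.integer(days),
    prednisone_equivalent_mg_total = mg, cost_ntd = cost
  )
}

mc_row <- function(id = "P1", setting = "outpatient", start = IDX, end = start,
                   dx = "7140", inj = FALSE, med = 0, nonmed = 0) {
  tibble::tibble(
    patient_id = id, setting = setting, start_date = as.Date(start),
    end_date = as.Date(end), diagnosis_codes = dx,
    is_gc_joint_injection = inj, medication_cost_ntd = med,
    nonmedication_cost_ntd = nonmed
  )
}

ci_row <- function(id = "P1", code = "7140", date = "2009-06-01") {
  tibble::tibble(
    patient_id = id, icd9_code = code, effective_date = as.Date(date)
  )
}

# A one-patient bundle that passes inclusion/exclusion with an index event at
# IDX; extra rows are appended to the relevant tables.
one_patient_bundle <- function(extra_ph = NULL, extra_mc = NULL,
                               index_agent = "etanercept",
                               enrollment = enroll_row()) {
  claims_bundle(
    enrollment = enrollment,
    catastrophic_illness = ci_row(),
    medical_claims = dplyr::bind_rows(mc_row(start = "2009-08-01"), extra_mc),
    pharmacy_claims = dplyr::bind_rows(
      ph_row(date = IDX, code = unname(claimsir:::AGENT_CODES[index_agent]), agent = index_agent),
      extra_ph
    )
  )
}

one_patient_cohort <- function(index_agent = "etanercept") {
  tibble::tibble(
    patient_id = "P1", index_date = IDX, index_agent = index_agent,
    age_at_index = 49L, sex = "female"
  )
}

# The calibrated preset pipeline is expensive; run it once per test session.
.run_cache <- new.env(parent = emptyenv())

preset_run <- function(seed = 42L) {
  key <- paste0("seed", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_pipeline(taiwan_2010_preset(rng_seed = seed))
  }
  .run_cache[[key]]
}

small_scenario <- function(n = 200L, seed = 11L, ...) {
  scenario_spec(n_patients = n, rng_seed = seed, ...)
}

# Brute-force day-enumeration PDC, the independent oracle for the
# interval-union implementation.
brute_pdc <- function(day, supply, window_days = 365L) {
  covered <- logical(window_days)
  for (i in seq_along(day)) {
    d <- seq(day[i], day[i] + supply[i] - 1)
    d <- d[d >= 0 & d < window_days]
    covered[d + 1] <- TRUE
  }
  sum(covered) / window_days
}
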