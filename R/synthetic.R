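#' @noRd
AGENT_CODES <- c(
  abatacept = "B-ABA", adalimumab = "B-ADA", etanercept = "B-ETA",
  golimumab = "B-GOL", tocilizumab = "B-TOC"
)

#' @noRd
CRITERIA <- c(
  "low_adherence", "switch_or_add", "new_csdmard",
  "gc_injections", "oral_gc_increase"
)

#' Scenario specification for the synthetic claims generator
#'
#' Describes a study population with planted ground truth: response-status
#' mix, per-criterion marginals among inadequate responders, index-drug mix,
#' three-year switching behaviour, per-cohort-year resource-use and cost
#' means, enrollment attrition across follow-up years, demography and
#' baseline comorbidity. All categorical quantities are planted as exact
#' counts (assignment without replacement), so cohort composition is
#' reproduced exactly rather than in expectation.
#'
#' @param n_patients Number of index patients (the final cohort size).
#' @param status_proportions Named proportions over `stable`, `IR`,
#'   `unknown`; must sum to 1.
#' @param criterion_marginals Named probabilities (among IR patients) for the
#'   five criteria; the planted per-criterion counts are
#'   `round(marginal * n_IR)` and every IR patient receives at least one
#'   flag, so the counts must sum to at least `n_IR`.
#' @param index_drug_mix Named proportions over index agents.
#' @param switch_probability_by_drug Named three-year switch probabilities
#'   per index agent.
#' @param switch_mean_days Named overall mean time to switch (days) per
#'   index agent, across early (criterion-2) and late switchers.
#' @param switch_destinations Named list (per index agent) of named
#'   destination proportions.
#' @param year_enrollment_by_status Named list of length-3 fractions of each
#'   status group continuously enrolled through follow-up years 1-3
#'   (stable/IR must be fully enrolled in year 1; unknown patients are
#'   censored inside year 1 by definition).
#' @param hcru_means Tibble with columns `cohort` (`stable`/`IR`), `year`,
#'   `admissions`, `hospital_days`, `ed_visits`, `outpatient_visits`:
#'   planted per-patient-year means.
#' @param cost_means_usd,cost_sds_usd Tibbles with columns `cohort`, `year`,
#'   `inpatient`, `outpatient`, `ed`, `medication` (2017 USD): planted
#'   per-patient-year cost means and SDs.
#' @param age_mean,age_sd,female_fraction Demography.
#' @param cci_mean_by_status Named target mean Charlson scores per status
#'   (>= 1; the rheumatic-disease category is always triggered).
#' @param gc_user_fraction Fraction of patients on maintenance oral
#'   glucocorticoids at baseline.
#' @param n_decoys Extra non-qualifying patients (one inclusion/exclusion
#'   violation each) added to exercise the attrition table.
#' @param rng_seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_patients,
                          status_proportions = c(stable = 0.32, IR = 0.66, unknown = 0.02),
                          criterion_marginals = c(
                            low_adherence = 0.545, switch_or_add = 0.046,
                            new_csdmard = 0.12, gc_injections = 0.257,
                            oral_gc_increase = 0.304
                          ),
                          index_drug_mix = c(adalimumab = 0.46, etanercept = 0.54),
                          switch_probability_by_drug = c(adalimumab = 0.21, etanercept = 0.13),
                          switch_mean_days = c(adalimumab = 782.4, etanercept = 755.6),
                          switch_destinations = list(
                            adalimumab = c(etanercept = 0.41, tocilizumab = 0.39, golimumab = 0.11, abatacept = 0.09),
                            etanercept = c(adalimumab = 0.54, tocilizumab = 0.23, golimumab = 0.14, abatacept = 0.09)
                          ),
                          year_enrollment_by_status = list(
                            stable = c(1, 1, 1), IR = c(1, 1, 1), unknown = c(0, 0, 0)
                          ),
                          hcru_means = default_hcru_means(),
                          cost_means_usd = default_cost_means(),
                          cost_sds_usd = default_cost_sds(),
                          age_mean = 55.5, age_sd = 13.1,
                          female_fraction = 0.84,
                          cci_mean_by_status = c(stable = 1.48, IR = 1.68, unknown = 2.75),
                          gc_user_fraction = 0.6,
                          n_decoys = 0L,
                          rng_seed = 1L) {
  spec <- structure(
    list(
      n_patients = as.integer(n_patients),
      status_proportions = status_proportions[c("stable", "IR", "unknown")],
      criterion_marginals = criterion_marginals[CRITERIA],
      index_drug_mix = index_drug_mix,
      switch_probability_by_drug = switch_probability_by_drug,
      switch_mean_days = switch_mean_days,
      switch_destinations = switch_destinations,
      year_enrollment_by_status = year_enrollment_by_status,
      hcru_means = hcru_means,
      cost_means_usd = cost_means_usd,
      cost_sds_usd = cost_sds_usd,
      age_mean = age_mean, age_sd = age_sd,
      female_fraction = female_fraction,
      cci_mean_by_status = cci_mean_by_status,
      gc_user_fraction = gc_user_fraction,
      n_decoys = as.integer(n_decoys),
      rng_seed = as.integer(rng_seed)
    ),
    class = "scenario_spec"
  )
  validate_scenario_spec(spec)
  spec
}

#' @noRd
validate_scenario_spec <- function(spec) {
  p <- spec$status_proportions
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort_claimsir("status_proportions must be non-negative and sum to 1.",
      "claimsir_spec_error")
  }
  m <- spec$criterion_marginals
  if (anyNA(m) || any(m < 0 | m > 1)) {
    abort_claimsir("criterion_marginals must lie in [0, 1].", "claimsir_spec_error")
  }
  if (p[["IR"]] > 0 && all(m == 0)) {
    abort_claimsir(
      "Infeasible spec: positive IR proportion with all criterion marginals zero.",
      "claimsir_spec_error"
    )
  }
  n_ir <- round(p[["IR"]] * spec$n_patients)
  if (n_ir > 0 && sum(round(m * n_ir)) < n_ir) {
    abort_claimsir(
      "Infeasible spec: criterion counts cannot give every IR patient a flag.",
      "claimsir_spec_error"
    )
  }
  if (abs(sum(spec$index_drug_mix) - 1) > 1e-9) {
    abort_claimsir("index_drug_mix must sum to 1.", "claimsir_spec_error")
  }
  for (d in names(spec$switch_destinations)) {
    dest <- spec$switch_destinations[[d]]
    if (d %in% names(dest)) {
      abort_claimsir("A switch destination equals its origin agent.", "claimsir_spec_error")
    }
  }
  for (s in c("stable", "IR")) {
    if (spec$year_enrollment_by_status[[s]][1] != 1) {
      abort_claimsir(
        "stable/IR patients must be fully enrolled through follow-up year 1.",
        "claimsir_spec_error"
      )
    }
  }
  invisible(spec)
}

#' @noRd
default_hcru_means <- function() {
  tibble::tibble(
    cohort = rep(c("stable", "IR"), each = 3),
    year = rep(1:3, 2),
    admissions = c(0.10, 0.27, 0.39, 0.46, 0.58, 0.63),
    hospital_days = c(0.49, 1.54, 1.95, 3.40, 2.74, 3.36),
    ed_visits = c(0.30, 0.45, 0.42, 0.51, 0.37, 0.46),
    outpatient_visits = c(37.66, 37.10, 37.79, 42.50, 39.96, 41.15)
  )
}

#' @noRd
default_cost_means <- function() {
  tibble::tibble(
    cohort = rep(c("stable", "IR"), each = 3),
    year = rep(1:3, 2),
    inpatient = c(104, 307, 394, 667, 522, 526),
    outpatient = c(803, 837, 834, 857, 855, 884),
    ed = c(30, 32, 38, 50, 35, 57),
    medication = c(15198, 11908, 10467, 12580, 9263, 8276)
  )
}

#' @noRd
default_cost_sds <- function() {
  tibble::tibble(
    cohort = rep(c("stable", "IR"), each = 3),
    year = rep(1:3, 2),
    inpatient = c(455, 1027, 1090, 1651, 1759, 1516),
    outpatient = c(1371, 1392, 1418, 610, 867, 700),
    ed = c(116, 124, 117, 131, 112, 142),
    medication = c(1464, 3486, 3987, 3918, 4966, 4906)
  )
}

#' Calibrated Taiwan 2010 scenario
#'
#' The generator preset emulating the published Taiwanese bDMARD new-user
#' cohort: exactly 818 index patients splitting 258 stable / 540 IR / 20
#' unknown after one year, 375 adalimumab / 443 etanercept initiators, 79
#' and 56 three-year switchers with the observed destination mix and mean
#' switch times of 782.4 / 755.6 days, overlapping criterion marginals of
#' 294/164/139/65/25 patients (36/20/17/8/3% of the cohort), per-cohort-year
#' resource-use and cost means from the published annual tables, and the
#' shrinking year-by-year enrolled counts (798/785/741 overall).
#'
#' @param rng_seed Integer seed.
#' @return A [scenario_spec()].
#' @export
taiwan_2010_preset <- function(rng_seed = 1L) {
  scenario_spec(
    n_patients = 818L,
    status_proportions = c(stable = 258, IR = 540, unknown = 20) / 818,
    criterion_marginals = c(
      low_adherence = 294, switch_or_add = 25, new_csdmard = 65,
      gc_injections = 139, oral_gc_increase = 164
    ) / 540,
    index_drug_mix = c(adalimumab = 375, etanercept = 443) / 818,
    switch_probability_by_drug = c(adalimumab = 79 / 375, etanercept = 56 / 443),
    switch_mean_days = c(adalimumab = 782.4, etanercept = 755.6),
    switch_destinations = list(
      adalimumab = c(etanercept = 32, tocilizumab = 31, golimumab = 9, abatacept = 7) / 79,
      etanercept = c(adalimumab = 30, tocilizumab = 13, golimumab = 8, abatacept = 5) / 56
    ),
    year_enrollment_by_status = list(
      stable = c(258, 256, 243) / 258,
      IR = c(540, 529, 498) / 540,
      unknown = c(0, 0, 0)
    ),
    age_mean = 55.5, age_sd = 13.1,
    female_fraction = 685 / 818,
    cci_mean_by_status = c(stable = 1.48, IR = 1.68, unknown = 2.75),
    n_decoys = 40L,
    rng_seed = rng_seed
  )
}

# ---- generation ------------------------------------------------------------

#' Generate a synthetic claims bundle with planted ground truth
#'
#' Emits enrollment, catastrophic-illness, medical and pharmacy claims such
#' that every planted criterion flag is realized by concrete claims and, by
#' construction, no unplanted criterion can fire under the supplied
#' configuration (stable patients keep PDC at or above the threshold, at
#' most one joint injection, no new compounds, non-increasing oral steroid
#' dose; unknown patients are censored with no prior criterion). Running the
#' cohort builder and classifier on the output therefore recovers the
#' planted labels exactly.
#'
#' @param spec A [scenario_spec()].
#' @param config A [study_config()]; thresholds and windows used both to
#'   realize and to guard the planted flags.
#' @return A list: `bundle` (a validated [claims_bundle()]), `truth`
#'   (per-patient planted labels, flags, switch and censor days) and `spec`.
#' @export
generate_claims <- function(spec, config = study_config()) {
  validate_scenario_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$rng_seed)

  n <- spec$n_patients
  fud <- config$follow_up_days
  idx_len <- as.integer(config$index_end - config$index_start) + 1L

  pt <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    status = sample(rep(names(spec$status_proportions),
      largest_remainder(spec$status_proportions, n))),
    index_date = config$index_start + sample.int(idx_len, n, replace = TRUE) - 1L,
    agent = sample(rep(names(spec$index_drug_mix),
      largest_remainder(spec$index_drug_mix, n))),
    sex = sample(rep(c("female", "male"),
      c(round(spec$female_fraction * n), n - round(spec$female_fraction * n)))),
    age = pmin(90L, pmax(20L, as.integer(round(stats::rnorm(n, spec$age_mean, spec$age_sd)))))
  )
  pt$birth_date <- pt$index_date - as.integer(floor(pt$age * 365.25)) - 180L
  pt$horizon_end_day <- as.integer(config$study_end - pt$index_date) + 1L

  # enrollment end (first uncovered day offset); NA-like sentinel = horizon end
  pt$end_day <- pt$horizon_end_day
  unk <- which(pt$status == "unknown")
  pt$end_day[unk] <- sample(30:334, length(unk), replace = TRUE)
  for (s in c("stable", "IR")) {
    rows <- which(pt$status == s)
    frac <- spec$year_enrollment_by_status[[s]]
    c1 <- length(rows)
    c2 <- round(frac[2] * c1)
    c3 <- round(frac[3] * c1)
    droppers <- sample_vec(rows, c1 - c3)
    d2 <- utils::head(droppers, c1 - c2)
    d3 <- utils::tail(droppers, c2 - c3)
    if (length(d2)) pt$end_day[d2] <- sample(366:700, length(d2), replace = TRUE)
    if (length(d3)) pt$end_day[d3] <- sample(731:1065, length(d3), replace = TRUE)
  }

  # criterion flags among IR patients: exact counts, every patient >= 1 flag
  flags <- matrix(FALSE, n, 5, dimnames = list(NULL, CRITERIA))
  ir <- which(pt$status == "IR")
  n_ir <- length(ir)
  if (n_ir > 0) {
    counts <- round(spec$criterion_marginals * n_ir)
    tokens <- sample(rep.int(seq_len(5), counts))
    first <- tokens[seq_len(n_ir)]
    flags[cbind(ir, first)] <- TRUE
    for (tok in tokens[-seq_len(n_ir)]) {
      open <- ir[!flags[ir, tok]]
      flags[open[sample.int(length(open), 1)], tok] <- TRUE
    }
  }

  # planted PDC in covered days over the one-year window
  thr <- config$pdc_threshold
  k <- as.integer(ceiling(stats::runif(n, thr, 1) * fud))
  low <- flags[, "low_adherence"]
  k[low] <- as.integer(floor(stats::runif(sum(low), 0.2, thr) * fud))
  k[unk] <- pt$end_day[unk]
  pt$pdc_days <- pmin(k, fud)

  # switching: early switchers are the criterion-2 patients; late switchers
  # are drawn from fully-enrolled patients so the per-agent overall mean
  # time to switch equals the planted target in expectation
  pt$switch_day <- NA_integer_
  pt$switch_to <- NA_character_
  for (d in names(spec$switch_probability_by_drug)) {
    drows <- which(pt$agent == d)
    n_sw <- round(spec$switch_probability_by_drug[[d]] * length(drows))
    early <- drows[flags[drows, "switch_or_add"]]
    n_sw <- max(n_sw, length(early))
    pt$switch_day[early] <- sample(30:364, length(early), replace = TRUE)
    n_late <- n_sw - length(early)
    if (n_late > 0) {
      cand <- drows[pt$end_day[drows] >= 1096 & !(drows %in% early)]
      if (length(cand) < n_late) {
        abort_claimsir(
          "Infeasible spec: not enough fully-enrolled patients to plant late switchers.",
          "claimsir_spec_error"
        )
      }
      late <- sample_vec(cand, n_late)
      # uniform window centred so the per-agent mean over early + late
      # switchers equals the planted target (clamped into [366, 1094])
      mu <- (spec$switch_mean_days[[d]] * n_sw - sum(pt$switch_day[early])) / n_late
      mu <- min(1094, max(366, mu))
      lo <- max(366, 2 * mu - 1094)
      hi <- min(1094, max(lo, 2 * mu - 366))
      pt$switch_day[late] <- pmin(1094L, pmax(366L, as.integer(round(stats::runif(n_late, lo, hi)))))
    } else {
      late <- integer(0)
    }
    sw <- c(early, late)
    if (length(sw)) {
      dest <- spec$switch_destinations[[d]]
      pt$switch_to[sw] <- sample(rep(names(dest), largest_remainder(dest, length(sw))))
    }
  }

  # baseline comorbidity: extra weight-1 Deyo categories, Poisson about the
  # per-status target mean minus the rheumatic-disease point
  comorbidity_pool <- c("25000", "4280", "4960", "5310", "5712", "4100", "2900", "4439", "4340")
  target <- spec$cci_mean_by_status[pt$status]
  n_extra <- pmin(length(comorbidity_pool), stats::rpois(n, pmax(0, target - 1)))
  extra_codes <- lapply(n_extra, function(m) sample(comorbidity_pool, m))

  gc_user <- stats::runif(n) < spec$gc_user_fraction
  gc_inc <- flags[, "oral_gc_increase"]
  gc_new_use <- gc_inc & stats::runif(n) < 0.5 # escalation vs new use

  ph <- list() # pharmacy pieces: row, day, code, class, agent, supply, mg
  mc <- list() # medical pieces: row, setting, day, len, dx, inj, med, nonmed

  ph_piece <- function(row, day, code, class, agent = NA_character_,
                       supply = 30L, mg = NA_real_) {
    tibble::tibble(
      row = row, day = as.integer(day), code = code, class = class,
      agent = agent, supply = as.integer(supply), mg = mg
    )
  }
  mc_piece <- function(row, day, setting, len = 0L, dx = "7140", inj = FALSE,
                       med = 0, nonmed = 0) {
    tibble::tibble(
      row = row, setting = setting, day = as.integer(day),
      len = as.integer(len), dx = dx, inj = inj, med = med, nonmed = nonmed
    )
  }
  seq_days <- function(rows, start, end_lim, by) {
    start <- rep(start, length.out = length(rows))
    m <- pmax(0, ceiling((end_lim - start) / by))
    list(row = rep(rows, m), day = rep(start, m) + (sequence(m) - 1) * by)
  }

  # 1. index-agent dispenses covering follow-up days [0, pdc_days)
  m1 <- ceiling(pt$pdc_days / 30)
  r1 <- rep(seq_len(n), m1)
  off1 <- (sequence(m1) - 1L) * 30L
  ph$index_y1 <- ph_piece(
    r1, off1, AGENT_CODES[pt$agent[r1]], "bDMARD", pt$agent[r1],
    pmin(30L, rep(pt$pdc_days, m1) - off1)
  )
  # 2. maintenance dispensing in years 2-3 while enrolled
  s2 <- seq_days(seq_len(n), 365, pmin(pt$end_day, 1095), 90)
  ph$index_y23 <- ph_piece(
    s2$row, s2$day, AGENT_CODES[pt$agent[s2$row]], "bDMARD", pt$agent[s2$row],
    supply = 90L
  )
  # 3. post-switch agent
  swr <- which(!is.na(pt$switch_day))
  if (length(swr)) {
    ph$switch <- ph_piece(
      rep(swr, 2), c(pt$switch_day[swr], pt$switch_day[swr] + 30L),
      AGENT_CODES[rep(pt$switch_to[swr], 2)], "bDMARD", rep(pt$switch_to[swr], 2)
    )
  }
  # 4. background csDMARDs (present pre-index, hence never "new")
  for (dd in list(
    list(code = "MTX", days = c(-350, -250, -150, -50, 20, 110, 200, 290)),
    list(code = "HCQ", days = c(-300, -100))
  )) {
    ph[[dd$code]] <- ph_piece(
      rep(seq_len(n), each = length(dd$days)),
      rep(dd$days, n), dd$code, "csDMARD"
    )
  }
  s3 <- seq_days(seq_len(n), 380, pmin(pt$end_day, 1095), 90)
  ph$mtx_y23 <- ph_piece(s3$row, s3$day, "MTX", "csDMARD", supply = 90L)
  # 5. new csDMARD for criterion-3 patients
  ncs <- which(flags[, "new_csdmard"])
  if (length(ncs)) {
    d0 <- sample(30:330, length(ncs), replace = TRUE)
    ph$lef <- ph_piece(rep(ncs, 2), c(d0, d0 + 30L), "LEF", "csDMARD")
  }
  # 6. oral glucocorticoids (prednisone-equivalent mg per dispense)
  pre_days <- seq(-360, -30, by = 30)
  cmp_days <- seq(95, 335, by = 30)
  with_pre_gc <- which((gc_user & !gc_inc) | (gc_inc & !gc_new_use))
  if (length(with_pre_gc)) {
    ph$gc_pre <- ph_piece(
      rep(with_pre_gc, each = 12), rep(pre_days, length(with_pre_gc)),
      "PRED", "oral_GC", mg = 5 * config$pre_index_days / 12
    )
    ph$gc_bridge <- ph_piece(with_pre_gc, 5L, "PRED", "oral_GC", mg = 300)
  }
  cmp_len <- fud - config$gc_bridging_exclusion_days
  gc_follow <- tibble::tibble(row = integer(0), dose = numeric(0))
  steady <- which(gc_user & !gc_inc & pt$status != "unknown")
  esc <- which(gc_inc & !gc_new_use)
  newu <- which(gc_new_use)
  gc_follow <- tibble::tibble(
    row = c(steady, esc, newu),
    dose = c(rep(4, length(steady)), rep(10, length(esc)), rep(2, length(newu)))
  )
  if (nrow(gc_follow)) {
    ph$gc_cmp <- ph_piece(
      rep(gc_follow$row, each = length(cmp_days)),
      rep(cmp_days, nrow(gc_follow)), "PRED", "oral_GC",
      mg = rep(gc_follow$dose * cmp_len / length(cmp_days), each = length(cmp_days))
    )
  }

  # 7. pre-index RA care and planted comorbidities
  ra_days <- -340 + (0:5) * 60
  mc$ra_base <- mc_piece(
    rep(seq_len(n), each = 6),
    rep(ra_days, n) + sample(0:19, 6 * n, replace = TRUE),
    "outpatient",
    nonmed = 500
  )
  cm_rows <- rep(seq_len(n), n_extra)
  if (length(cm_rows)) {
    mc$comorbid <- mc_piece(
      cm_rows, sample(-360:-30, length(cm_rows), replace = TRUE),
      "outpatient", dx = unlist(extra_codes), nonmed = 500
    )
  }
  # 8. glucocorticoid joint injections
  inj_n <- integer(n)
  ginj <- flags[, "gc_injections"]
  inj_n[ginj] <- 2L + stats::rbinom(sum(ginj), 1L, 0.3)
  not_flagged <- pt$status != "unknown" & !ginj
  inj_n[not_flagged] <- stats::rbinom(sum(not_flagged), 1L, 0.15)
  inj_rows <- rep(seq_len(n), inj_n)
  if (length(inj_rows)) {
    mc$injections <- mc_piece(
      inj_rows, sample(10:350, length(inj_rows), replace = TRUE),
      "outpatient", inj = TRUE
    )
  }

  # 9. follow-up utilization at the planted per-cohort-year means
  py <- tidyr::expand_grid(row = seq_len(n), year = 1:3)
  py$status <- pt$status[py$row]
  py <- py[py$status %in% c("stable", "IR") & pt$end_day[py$row] >= py$year * 365, ]
  hm <- spec$hcru_means
  hidx <- match(paste(py$status, py$year), paste(hm$cohort, hm$year))
  py$n_op <- pmax(1L, stats::rpois(nrow(py), hm$outpatient_visits[hidx]))
  py$n_adm <- stats::rpois(nrow(py), hm$admissions[hidx])
  py$n_ed <- stats::rpois(nrow(py), hm$ed_visits[hidx])
  py$day_ratio <- hm$hospital_days[hidx] / pmax(hm$admissions[hidx], 1e-9)

  # outpatient visits beyond those already emitted as injections (year 1)
  inj_y1 <- integer(n)
  if (length(inj_rows)) {
    tab <- table(inj_rows)
    inj_y1[as.integer(names(tab))] <- as.integer(tab)
  }
  existing <- ifelse(py$year == 1, inj_y1[py$row], 0L)
  n_extra_op <- pmax(0L, py$n_op - existing)
  op_rows <- rep(py$row, n_extra_op)
  op_year <- rep(py$year, n_extra_op)
  mc$visits <- mc_piece(
    op_rows,
    (op_year - 1) * 365 + sample.int(365, length(op_rows), replace = TRUE) - 1L,
    "outpatient"
  )
  # partial-year visits for censored patients (excluded from summaries)
  if (length(unk)) {
    n_unk_op <- stats::rpois(length(unk), 40 * pt$end_day[unk] / 365)
    unk_rows <- rep(unk, n_unk_op)
    if (length(unk_rows)) {
      ends <- rep(pt$end_day[unk], n_unk_op)
      mc$unk_visits <- mc_piece(
        unk_rows, floor(stats::runif(length(unk_rows)) * ends), "outpatient"
      )
    }
  }
  # admissions and ED visits, with per-event costs whose compound mean
  # matches the planted per-patient-year cost cell
  cm <- spec$cost_means_usd
  cs <- spec$cost_sds_usd
  rate <- config$exchange_rate_usd_per_ntd
  cidx <- match(paste(py$status, py$year), paste(cm$cohort, cm$year))
  adm_rows <- rep(seq_len(nrow(py)), py$n_adm)
  if (length(adm_rows)) {
    per_adm_mean <- (cm$inpatient[cidx] / rate) / pmax(hm$admissions[hidx], 1e-9)
    mc$admissions <- mc_piece(
      py$row[adm_rows],
      (py$year[adm_rows] - 1) * 365 + sample.int(365, length(adm_rows), replace = TRUE) - 1L,
      "inpatient",
      len = 1L + stats::rpois(length(adm_rows), pmax(0, py$day_ratio[adm_rows] - 1)),
      nonmed = round(rlnorm_meansd(
        length(adm_rows), 1, 1
      ) * per_adm_mean[adm_rows])
    )
  }
  ed_rows <- rep(seq_len(nrow(py)), py$n_ed)
  if (length(ed_rows)) {
    per_ed_mean <- (cm$ed[cidx] / rate) / pmax(hm$ed_visits[hidx], 1e-9)
    mc$ed <- mc_piece(
      py$row[ed_rows],
      (py$year[ed_rows] - 1) * 365 + sample.int(365, length(ed_rows), replace = TRUE) - 1L,
      "ED",
      nonmed = round(rlnorm_meansd(length(ed_rows), 1, 1) * per_ed_mean[ed_rows])
    )
  }

  ph_all <- dplyr::bind_rows(ph)
  mc_all <- dplyr::bind_rows(mc)
  # nothing is observed on or after the enrollment end
  ph_all <- ph_all[ph_all$day < pt$end_day[ph_all$row], ]
  mc_all <- mc_all[mc_all$day < pt$end_day[mc_all$row], ]

  # 10. per-patient-year outpatient and medication cost totals (log-normal
  # with the planted mean and printed SD), spread over carrier claims
  py$O <- round(rlnorm_meansd(nrow(py), cm$outpatient[cidx] / rate, cs$outpatient[cidx] / rate))
  py$M <- round(rlnorm_meansd(nrow(py), cm$medication[cidx] / rate, cs$medication[cidx] / rate))
  pykey <- paste(py$row, py$year)

  mc_all$year <- mc_all$day %/% 365 + 1
  mck <- paste(mc_all$row, mc_all$year)
  is_op_fu <- mc_all$setting == "outpatient" & mc_all$day >= 0 & mck %in% pykey
  op_counts <- table(mck[is_op_fu])
  pidx <- match(mck, pykey)
  share <- ifelse(is_op_fu, 1 / as.integer(op_counts[mck]), 0)
  mc_all$nonmed <- ifelse(is_op_fu, round(py$O[pidx] * share), mc_all$nonmed)
  mc_all$med <- ifelse(is_op_fu, round(0.1 * py$M[pidx] * share), mc_all$med)

  ph_all$year <- ph_all$day %/% 365 + 1
  phk <- paste(ph_all$row, ph_all$year)
  is_ph_fu <- ph_all$day >= 0 & phk %in% pykey
  ph_counts <- table(phk[is_ph_fu])
  ppidx <- match(phk, pykey)
  ph_all$cost <- ifelse(is_ph_fu,
    round(0.9 * py$M[ppidx] / as.integer(ph_counts[phk])),
    ifelse(ph_all$day < 0, 200, 0)
  )

  # assemble the bundle tables
  enrollment <- tibble::tibble(
    patient_id = pt$patient_id,
    birth_date = pt$birth_date,
    sex = pt$sex,
    coverage_start = config$study_start,
    coverage_end = pt$index_date + pt$end_day - 1L,
    death_date = as.Date(NA)
  )
  cat_ill <- tibble::tibble(
    patient_id = pt$patient_id,
    icd9_code = "7140",
    effective_date = pt$index_date - sample(30:300, n, replace = TRUE)
  )
  medical <- tibble::tibble(
    patient_id = pt$patient_id[mc_all$row],
    setting = mc_all$setting,
    start_date = pt$index_date[mc_all$row] + mc_all$day,
    end_date = pt$index_date[mc_all$row] + mc_all$day +
      ifelse(mc_all$setting == "inpatient", mc_all$len, 0L),
    diagnosis_codes = mc_all$dx,
    is_gc_joint_injection = mc_all$inj,
    medication_cost_ntd = mc_all$med,
    nonmedication_cost_ntd = mc_all$nonmed
  )
  pharmacy <- tibble::tibble(
    patient_id = pt$patient_id[ph_all$row],
    dispense_date = pt$index_date[ph_all$row] + ph_all$day,
    drug_code = ph_all$code,
    drug_class = ph_all$class,
    bdmard_agent = ph_all$agent,
    days_supplied = ph_all$supply,
    prednisone_equivalent_mg_total = ph_all$mg,
    cost_ntd = ph_all$cost
  )

  decoys <- make_decoys(spec, config)
  bundle <- claims_bundle(
    enrollment = dplyr::bind_rows(enrollment, decoys$enrollment) |>
      dplyr::arrange(.data$patient_id, .data$coverage_start),
    catastrophic_illness = dplyr::bind_rows(cat_ill, decoys$catastrophic_illness),
    medical_claims = dplyr::bind_rows(medical, decoys$medical_claims) |>
      dplyr::arrange(.data$patient_id, .data$start_date, .data$setting),
    pharmacy_claims = dplyr::bind_rows(pharmacy, decoys$pharmacy_claims) |>
      dplyr::arrange(.data$patient_id, .data$dispense_date, .data$drug_code)
  )
  truth <- tibble::tibble(
    patient_id = pt$patient_id,
    status = unname(c(stable = "Stable", IR = "IR", unknown = "Unknown")[pt$status]),
    low_adherence = flags[, 1], switch_or_add = flags[, 2],
    new_csdmard = flags[, 3], gc_injections = flags[, 4],
    oral_gc_increase = flags[, 5],
    index_date = pt$index_date,
    index_agent = pt$agent,
    pdc_days = pt$pdc_days,
    censor_day = ifelse(pt$status == "unknown", pt$end_day, NA_integer_),
    enrollment_end_day = pt$end_day,
    switch_day = pt$switch_day,
    switch_to = pt$switch_to,
    age = pt$age, sex = pt$sex,
    cci_planted = 1L + n_extra
  )
  truth <- dplyr::bind_rows(truth, decoys$truth)
  list(bundle = bundle, truth = truth, spec = spec)
}

# Non-qualifying patients, one inclusion/exclusion violation each, cycled
# over the seven violation types.
#' @noRd
make_decoys <- function(spec, config) {
  nd <- spec$n_decoys
  empty <- list(
    enrollment = NULL, catastrophic_illness = NULL,
    medical_claims = NULL, pharmacy_claims = NULL, truth = NULL
  )
  if (nd == 0) {
    return(empty)
  }
  types <- rep(c(
    "prior_bdmard", "no_ra_code", "no_card", "underage",
    "no_preindex_enrollment", "inflammatory_dx", "malignancy_dx"
  ), length.out = nd)
  id <- sprintf("D%04d", seq_len(nd))
  idx_len <- as.integer(config$index_end - config$index_start) + 1L
  index_date <- config$index_start + sample.int(idx_len, nd, replace = TRUE) - 1L
  age <- ifelse(types == "underage", 16L, 45L)
  enrollment <- tibble::tibble(
    patient_id = id,
    birth_date = index_date - as.integer(age * 365.25) - 10L,
    sex = rep(c("female", "male"), length.out = nd),
    coverage_start = dplyr::if_else(types == "no_preindex_enrollment",
      index_date - 100L, config$study_start),
    coverage_end = config$study_end,
    death_date = as.Date(NA)
  )
  cat_ill <- tibble::tibble(
    patient_id = id[types != "no_card"],
    icd9_code = "7140",
    effective_date = index_date[types != "no_card"] - 60L
  )
  ra_dx <- ifelse(types == "no_ra_code", "4659", "7140")
  medical <- tibble::tibble(
    patient_id = id,
    setting = "outpatient",
    start_date = pmax(index_date - 90L, enrollment$coverage_start),
    end_date = pmax(index_date - 90L, enrollment$coverage_start),
    diagnosis_codes = ra_dx,
    is_gc_joint_injection = FALSE,
    medication_cost_ntd = 0,
    nonmedication_cost_ntd = 400
  )
  viol <- types %in% c("inflammatory_dx", "malignancy_dx")
  if (any(viol)) {
    medical <- dplyr::bind_rows(medical, tibble::tibble(
      patient_id = id[viol],
      setting = "outpatient",
      start_date = index_date[viol] + 500L,
      end_date = index_date[viol] + 500L,
      diagnosis_codes = ifelse(types[viol] == "inflammatory_dx", "6961", "1539"),
      is_gc_joint_injection = FALSE,
      medication_cost_ntd = 0,
      nonmedication_cost_ntd = 400
    ))
  }
  pharmacy <- tibble::tibble(
    patient_id = id,
    dispense_date = index_date,
    drug_code = "B-ETA",
    drug_class = "bDMARD",
    bdmard_agent = "etanercept",
    days_supplied = 30L,
    prednisone_equivalent_mg_total = NA_real_,
    cost_ntd = 30000
  )
  prior <- types == "prior_bdmard"
  if (any(prior)) {
    pharmacy <- dplyr::bind_rows(pharmacy, tibble::tibble(
      patient_id = id[prior],
      dispense_date = as.Date("2009-06-15"),
      drug_code = "B-ETA",
      drug_class = "bDMARD",
      bdmard_agent = "etanercept",
      days_supplied = 30L,
      prednisone_equivalent_mg_total = NA_real_,
      cost_ntd = 30000
    ))
  }
  truth <- tibble::tibble(
    patient_id = id, status = "Decoy",
    index_date = index_date, index_agent = "etanercept",
    decoy_type = types
  )
  list(
    enrollment = enrollment, catastrophic_illness = cat_ill,
    medical_claims = medical, pharmacy_claims = pharmacy, truth = truth
  )
}

#' Add non-informative nuisance claims
#'
#' Appends outpatient visits whose diagnoses match no inclusion, exclusion,
#' criterion or Charlson code list, with zero cost; the planted ground truth
#' and every downstream classification are unchanged.
#'
#' @param bundle A [claims_bundle()].
#' @param intensity Mean extra claims per patient-year (over a three-year
#'   span from each patient's first coverage day).
#' @param rng_seed Integer seed.
#' @return A new [claims_bundle()].
#' @export
add_nuisance_claims <- function(bundle, intensity, rng_seed = 1L) {
  stopifnot(intensity >= 0)
  if (intensity == 0) {
    return(bundle)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rng_seed)
  en <- bundle$enrollment |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      start = min(.data$coverage_start), end = max(.data$coverage_end),
      .groups = "drop"
    )
  span <- pmin(3 * 365, as.numeric(en$end - en$start) + 1)
  n_claims <- stats::rpois(nrow(en), intensity * span / 365)
  rows <- rep(seq_len(nrow(en)), n_claims)
  if (length(rows) == 0) {
    return(bundle)
  }
  pool <- c("460", "4660", "5990", "7295", "3829")
  extra <- tibble::tibble(
    patient_id = en$patient_id[rows],
    setting = "outpatient",
    start_date = en$start[rows] +
      floor(stats::runif(length(rows)) * rep(span, n_claims)),
    end_date = as.Date(NA),
    diagnosis_codes = sample(pool, length(rows), replace = TRUE),
    is_gc_joint_injection = FALSE,
    medication_cost_ntd = 0,
    nonmedication_cost_ntd = 0
  )
  extra$end_date <- extra$start_date
  claims_bundle(
    enrollment = bundle$enrollment,
    catastrophic_illness = bundle$catastrophic_illness,
    medical_claims = dplyr::bind_rows(bundle$medical_claims, extra),
    pharmacy_claims = bundle$pharmacy_claims
  )
}
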