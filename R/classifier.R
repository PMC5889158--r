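#' Proportion of days covered
#'
#' PDC is the size of the union of per-dispense coverage intervals
#' `[dispense_date, dispense_date + days_supplied)` intersected with the
#' observation window, divided by the window length. Overlapping supplies
#' collapse through the union; there is no stockpiling shift.
#'
#' @param dispense_dates Dates of index-agent dispenses.
#' @param days_supplied Integer days supplied per dispense (must be >= 1).
#' @param window_start Date the window opens (typically the index date).
#' @param window_days Window length in days; the window is
#'   `[window_start, window_start + window_days)`.
#' @return PDC in `[0, 1]`.
#' @export
#' @examples
#' compute_pdc(as.Date("2010-01-01"), 365, as.Date("2010-01-01"), 365) # 1
compute_pdc <- function(dispense_dates, days_supplied, window_start,
                        window_days = 365L) {
  if (any(days_supplied < 1)) {
    abort_claimsir("days_supplied below 1 in PDC computation.", "claimsir_invariant_error")
  }
  lo <- as.numeric(as.Date(window_start))
  covered <- covered_days(
    as.numeric(dispense_dates), as.numeric(dispense_dates) + days_supplied,
    lo, lo + window_days
  )
  covered / window_days
}

#' Detect a biologic switch or add
#'
#' @param pharmacy Pharmacy claims for one patient.
#' @param index_agent The index bDMARD agent.
#' @param window_start Date, start of the (half-open) detection window.
#' @param window_days Window length in days.
#' @return A list: `flag` and `first_date` (NA when no event).
#' @export
detect_switch_or_add <- function(pharmacy, index_agent, window_start,
                                 window_days = 365L) {
  lo <- as.Date(window_start)
  hi <- lo + window_days
  ph <- pharmacy[pharmacy$drug_class == "bDMARD" &
    !is.na(pharmacy$bdmard_agent) &
    pharmacy$bdmard_agent != index_agent &
    pharmacy$dispense_date >= lo & pharmacy$dispense_date < hi, ]
  list(
    flag = nrow(ph) > 0,
    first_date = if (nrow(ph)) min(ph$dispense_date) else as.Date(NA)
  )
}

#' Detect the addition of a new conventional synthetic DMARD
#'
#' A compound is new when it has at least one dispense strictly after the
#' index date inside the follow-up window and none in the pre-index window or
#' on the index date itself.
#'
#' @param pharmacy Pharmacy claims for one patient.
#' @param index_date Index date.
#' @param pre_index_days,window_days Pre-index and follow-up lengths (days).
#' @param follow_end_day Optional right bound (day offset, exclusive) when
#'   follow-up is censored; defaults to `window_days`.
#' @return A list: `flag` and `first_date`.
#' @export
detect_new_csdmard <- function(pharmacy, index_date, pre_index_days = 365L,
                               window_days = 365L, follow_end_day = NULL) {
  hi <- window_days
  if (!is.null(follow_end_day)) {
    hi <- min(hi, follow_end_day)
  }
  cs <- pharmacy[pharmacy$drug_class == "csDMARD", ]
  day <- as.numeric(cs$dispense_date) - as.numeric(as.Date(index_date))
  prior <- unique(cs$drug_code[day >= -pre_index_days & day <= 0])
  fu <- cs[day >= 1 & day < hi & !(cs$drug_code %in% prior), ]
  list(
    flag = nrow(fu) > 0,
    first_date = if (nrow(fu)) min(fu$dispense_date) else as.Date(NA)
  )
}

#' Count glucocorticoid joint injections
#'
#' @param medical Medical claims for one patient.
#' @param window_start Date, start of the detection window.
#' @param window_days Window length in days.
#' @param min_count Injections needed to flag (default 2, "more than one").
#' @return A list: `count`, `flag`, `first_date` (date of the
#'   `min_count`-th injection, NA unless flagged).
#' @export
count_gc_injections <- function(medical, window_start, window_days = 365L,
                                min_count = 2L) {
  lo <- as.Date(window_start)
  hi <- lo + window_days
  inj <- medical$start_date[medical$is_gc_joint_injection &
    medical$start_date >= lo & medical$start_date < hi]
  n <- length(inj)
  list(
    count = n,
    flag = n >= min_count,
    first_date = if (n >= min_count) sort(inj)[min_count] else as.Date(NA)
  )
}

#' Detect an oral glucocorticoid dose increase
#'
#' Compares the mean daily prednisone-equivalent dose over the follow-up
#' comparison window (follow-up days `[bridging_days, follow_end_day)`, the
#' first `bridging_days` days being excluded as routine bridging at biologic
#' start) with the mean daily dose over the pre-index window. The criterion
#' requires at least one oral glucocorticoid dispense in the comparison
#' window and a strict increase beyond the configured margin; new use over a
#' steroid-free baseline therefore counts.
#'
#' @param pharmacy Pharmacy claims for one patient.
#' @param index_date Index date.
#' @param config A [study_config()].
#' @param follow_end_day Day offset (exclusive) ending follow-up, defaults to
#'   the configured follow-up length; pass the censor day for censored
#'   patients.
#' @return A list: `flag`, `pre_mean`, `follow_mean`, `first_date`.
#' @export
detect_oral_gc_increase <- function(pharmacy, index_date,
                                    config = study_config(),
                                    follow_end_day = NULL) {
  gc <- pharmacy[pharmacy$drug_class == "oral_GC", ]
  day <- as.numeric(gc$dispense_date) - as.numeric(as.Date(index_date))
  pre_mean <- sum(gc$prednisone_equivalent_mg_total[day >= -config$pre_index_days & day < 0]) /
    config$pre_index_days
  hi <- min(config$follow_up_days, follow_end_day %||% config$follow_up_days)
  lo <- config$gc_bridging_exclusion_days
  len <- hi - lo
  in_cmp <- day >= lo & day < hi
  if (len <= 0 || !any(in_cmp)) {
    return(list(
      flag = FALSE, pre_mean = pre_mean, follow_mean = NA_real_,
      first_date = as.Date(NA)
    ))
  }
  follow_mean <- sum(gc$prednisone_equivalent_mg_total[in_cmp]) / len
  list(
    flag = follow_mean > pre_mean * (1 + config$gc_increase_margin_pct / 100),
    pre_mean = pre_mean,
    follow_mean = follow_mean,
    first_date = min(gc$dispense_date[in_cmp])
  )
}

# Censoring: merge coverage (death-truncated) bridging sub-tolerance gaps,
# take the interval containing the index date and see whether it reaches the
# end of follow-up. Returns NA (uncensored) or the first uncovered day offset.
#' @noRd
censor_day_for <- function(coverage, death_date, index_date, follow_up_days,
                           tolerance_days) {
  if (nrow(coverage) == 0) {
    return(0L)
  }
  e <- as.numeric(coverage$coverage_end)
  if (length(death_date) && !is.na(death_date[1])) {
    e <- pmin(e, as.numeric(death_date[1]))
  }
  s <- as.numeric(coverage$coverage_start)
  keep <- e >= s
  if (!any(keep)) {
    return(0L)
  }
  merged <- merge_intervals(s[keep], e[keep], tolerance = tolerance_days)
  idx <- as.numeric(index_date)
  row <- which(merged$start <= idx & merged$end >= idx)
  if (length(row) == 0) {
    return(0L)
  }
  last_needed <- idx + follow_up_days - 1
  cov_end <- merged$end[row[1]]
  if (cov_end >= last_needed ||
    last_needed - cov_end < tolerance_days) { # trailing gap short enough to ignore
    return(NA_integer_)
  }
  as.integer(cov_end - idx + 1)
}

# First day offset at which the PDC criterion becomes unreachable: the day
# after the m-th uncovered day, where m = floor((1 - threshold) * window) + 1.
#' @noRd
pdc_failure_day <- function(dispense_day, days_supplied, window_days, threshold) {
  covered <- rep(FALSE, window_days)
  for (i in seq_along(dispense_day)) {
    lo <- max(0, dispense_day[i])
    hi <- min(window_days, dispense_day[i] + days_supplied[i])
    if (hi > lo) {
      covered[(lo + 1):hi] <- TRUE
    }
  }
  uncovered <- which(!covered) - 1 # day offsets
  m <- floor((1 - threshold) * window_days) + 1
  if (length(uncovered) < m) {
    return(NA_integer_)
  }
  as.integer(uncovered[m])
}

#' Classify response for every cohort patient
#'
#' Evaluates the five inadequate-response criteria over the one-year
#' follow-up: (1) low adherence (PDC strictly below the threshold), (2) a
#' switch to or add of a second bDMARD, (3) the addition of a new
#' conventional synthetic DMARD, (4) glucocorticoid joint injections at or
#' above the configured count, (5) an oral glucocorticoid dose increase. A
#' patient whose enrollment ends (death or a coverage gap at or beyond the
#' tolerance) before follow-up closes and who met no criterion before the
#' censor day has Unknown status; otherwise any met criterion makes the
#' patient an inadequate responder (IR) and meeting none makes them Stable.
#' The index dose-increase criterion of the original algorithm is omitted:
#' Taiwanese reimbursement rules do not permit bDMARD dose increases.
#'
#' For censored patients the adherence criterion counts as met only when the
#' threshold had already become unreachable by the censor day; other criteria
#' are evaluated on claims before the censor day.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()].
#' @return A tibble with one row per patient: `status` (`Stable`/`IR`/
#'   `Unknown`), `pdc`, the five criterion flags, `first_criterion`,
#'   `first_criterion_date`, `censor_day`.
#' @export
classify_response <- function(cohort, bundle, config = study_config()) {
  en <- bundle$enrollment
  missing_pt <- setdiff(cohort$patient_id, en$patient_id)
  if (length(missing_pt)) {
    abort_claimsir(
      sprintf(
        "Cohort patient(s) absent from the enrollment table: %s",
        paste(utils::head(missing_pt, 5), collapse = ", ")
      ),
      "claimsir_invariant_error"
    )
  }
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      patient_id = character(0), status = character(0), pdc = numeric(0),
      low_adherence = logical(0), switch_or_add = logical(0),
      new_csdmard = logical(0), gc_injections = logical(0),
      oral_gc_increase = logical(0), first_criterion = character(0),
      first_criterion_date = as.Date(character(0)), censor_day = integer(0)
    ))
  }
  cov_by_pt <- split(
    en[c("coverage_start", "coverage_end", "death_date")],
    en$patient_id
  )
  ph_by_pt <- split_for(bundle$pharmacy_claims, cohort$patient_id)
  inj <- bundle$medical_claims[bundle$medical_claims$is_gc_joint_injection, ]
  inj_by_pt <- split_for(inj, cohort$patient_id)
  empty_ph <- empty_table(table_schemas()$pharmacy_claims)
  empty_mc <- empty_table(table_schemas()$medical_claims)
  fud <- config$follow_up_days

  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    idx <- cohort$index_date[i]
    agent <- cohort$index_agent[i]
    ph <- ph_by_pt[[pid]] %||% empty_ph
    mc <- inj_by_pt[[pid]] %||% empty_mc
    cov <- cov_by_pt[[pid]]

    censor <- censor_day_for(
      cov, cov$death_date, idx, fud, config$enrollment_gap_tolerance_days
    )
    w_end <- if (is.na(censor)) fud else censor

    own <- ph[ph$drug_class == "bDMARD" & !is.na(ph$bdmard_agent) &
      ph$bdmard_agent == agent, ]
    d_day <- as.numeric(own$dispense_date) - as.numeric(idx)
    covered <- covered_days(d_day, d_day + own$days_supplied, 0, w_end)
    pdc <- covered / fud
    # adherence fails once enough days are uncovered that the threshold is
    # unreachable even under full coverage from here on
    need <- ceiling(config$pdc_threshold * fud - 1e-9)
    low_adh <- covered + (fud - w_end) < need
    adh_date <- as.Date(NA)
    if (low_adh) {
      adh_date <- idx + pdc_failure_day(d_day, own$days_supplied, fud, config$pdc_threshold)
    }

    sw <- detect_switch_or_add(ph, agent, idx, w_end)
    cs <- detect_new_csdmard(ph, idx, config$pre_index_days, fud, w_end)
    gi <- count_gc_injections(mc, idx, w_end, config$gc_injection_min_count)
    gd <- detect_oral_gc_increase(ph, idx, config, follow_end_day = w_end)

    flags <- c(
      low_adherence = low_adh, switch_or_add = sw$flag,
      new_csdmard = cs$flag, gc_injections = gi$flag,
      oral_gc_increase = gd$flag
    )
    dates <- c(adh_date, sw$first_date, cs$first_date, gi$first_date, gd$first_date)
    status <- if (!is.na(censor) && !any(flags)) {
      "Unknown"
    } else if (any(flags)) {
      "IR"
    } else {
      "Stable"
    }
    first_idx <- if (any(flags)) {
      cand <- which(flags)
      cand[which.min(as.numeric(dates[cand]))]
    } else {
      NA_integer_
    }
    tibble::tibble(
      patient_id = pid,
      status = status,
      pdc = pdc,
      low_adherence = flags[[1]], switch_or_add = flags[[2]],
      new_csdmard = flags[[3]], gc_injections = flags[[4]],
      oral_gc_increase = flags[[5]],
      first_criterion = if (is.na(first_idx)) NA_character_ else names(flags)[first_idx],
      first_criterion_date = if (is.na(first_idx)) as.Date(NA) else dates[first_idx],
      censor_day = censor
    )
  })
  dplyr::bind_rows(rows)
}

#' @noRd
split_for <- function(df, ids) {
  df <- df[df$patient_id %in% ids, ]
  split(df, df$patient_id)
}

#' Per-criterion attribution
#'
#' Reports, for each of the five criteria, both the overlapping marginal
#' (share of the cohort meeting the flag, counting multi-criterion patients
#' under every flag they meet) and the first-met attribution (share of the
#' cohort whose earliest-dated criterion it is, ties broken by the fixed
#' criterion order).
#'
#' @param results Classification tibble from [classify_response()].
#' @return A tibble: `criterion`, `n_marginal`, `pct_marginal`,
#'   `n_first_met`, `pct_first_met` (percentages of the whole cohort).
#' @export
attribute_criteria <- function(results) {
  crit <- c(
    "low_adherence", "switch_or_add", "new_csdmard",
    "gc_injections", "oral_gc_increase"
  )
  n <- nrow(results)
  n_marginal <- vapply(crit, function(cc) sum(results[[cc]]), integer(1))
  n_first <- vapply(
    crit, function(cc) sum(results$first_criterion == cc, na.rm = TRUE),
    integer(1)
  )
  tibble::tibble(
    criterion = crit,
    n_marginal = unname(n_marginal),
    pct_marginal = if (n) 100 * unname(n_marginal) / n else rep(0, 5),
    n_first_met = unname(n_first),
    pct_first_met = if (n) 100 * unname(n_first) / n else rep(0, 5)
  )
}
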