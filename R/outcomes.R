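#' Convert NT$ to USD
#'
#' @param amount_ntd Non-negative NT$ amounts.
#' @param rate USD per NT$ (default 0.033).
#' @param digits Decimal places for half-up rounding; reported means use
#'   whole dollars (`digits = 0`). `NULL` returns the unrounded product.
#' @return USD amounts.
#' @export
#' @examples
#' convert_currency(445314) # 14695
convert_currency <- function(amount_ntd, rate = 0.033, digits = 0) {
  if (rate <= 0) {
    abort_claimsir("Exchange rate must be positive.", "claimsir_config_error")
  }
  if (any(amount_ntd < 0, na.rm = TRUE)) {
    abort_claimsir("Negative amount in currency conversion.", "claimsir_config_error")
  }
  usd <- amount_ntd * rate
  if (is.null(digits)) usd else round_half_up(usd, digits)
}

#' @noRd
year_enrolled <- function(cohort, bundle, config, year) {
  en <- bundle$enrollment
  cov_by_pt <- split(en[c("coverage_start", "coverage_end")], en$patient_id)
  vapply(seq_len(nrow(cohort)), function(i) {
    cov <- cov_by_pt[[cohort$patient_id[i]]]
    !is.null(cov) && check_continuous_enrollment(
      cov,
      cohort$index_date[i] + (year - 1) * 365L,
      cohort$index_date[i] + year * 365L,
      config$enrollment_gap_tolerance_days
    )
  }, logical(1))
}

#' Annualized resource use and direct costs for one follow-up year
#'
#' Per-patient quantities are summed inside the year window
#' `[index + 365 (k - 1), index + 365 k)` and averaged over patients
#' continuously enrolled through that window. Hospital admissions are counted
#' at the admission date; hospital days are discharge minus admission dates
#' with a minimum of one day for same-day stays. Costs are split into
#' inpatient, outpatient and ED (non-medication claim lines by setting) and
#' medication (pharmacy claims plus medication lines of medical claims);
#' the per-patient total is the sum of the four categories by construction.
#'
#' @param cohort Cohort tibble (needs `patient_id`, `index_date`).
#' @param results Classification tibble from [classify_response()]; used to
#'   form the `stable` and `IR` cohorts alongside `all`.
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()].
#' @param year Follow-up year, 1, 2 or 3.
#' @return A tibble with one row per cohort label (`all`, `stable`, `IR`):
#'   `n`, mean and SD of admissions, hospital days, ED visits, outpatient
#'   visits, and of the five cost categories in NT$ plus USD means.
#' @export
summarize_year <- function(cohort, results, bundle, config = study_config(),
                           year = 1) {
  if (!year %in% 1:3) {
    abort_claimsir("year must be 1, 2 or 3.", "claimsir_config_error")
  }
  per <- patient_year_quantities(cohort, bundle, year)
  enrolled <- year_enrolled(cohort, bundle, config, year)
  status <- stats::setNames(results$status, results$patient_id)[cohort$patient_id]
  groups <- list(
    all = enrolled,
    stable = enrolled & status == "Stable",
    IR = enrolled & status == "IR"
  )
  purrr::map_dfr(names(groups), function(g) {
    sel <- per[groups[[g]], , drop = FALSE]
    msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
    qty <- c("admissions", "hospital_days", "ed_visits", "outpatient_visits")
    cost <- c("inpatient_ntd", "outpatient_ntd", "ed_ntd", "medication_ntd", "total_ntd")
    stats_q <- lapply(per[, c(qty, cost)][groups[[g]], , drop = FALSE], msd)
    out <- tibble::tibble(cohort = g, year = year, n = nrow(sel))
    for (v in c(qty, cost)) {
      out[[paste0(v, "_mean")]] <- unname(stats_q[[v]]["mean"])
      out[[paste0(v, "_sd")]] <- unname(stats_q[[v]]["sd"])
    }
    for (v in cost) {
      out[[sub("_ntd$", "_usd_mean", v)]] <-
        convert_currency(out[[paste0(v, "_mean")]], config$exchange_rate_usd_per_ntd, NULL)
    }
    out
  })
}

#' @noRd
patient_year_quantities <- function(cohort, bundle, year) {
  idx <- stats::setNames(as.numeric(cohort$index_date), cohort$patient_id)
  lo <- (year - 1) * 365
  hi <- year * 365

  mc <- bundle$medical_claims
  mc <- mc[mc$patient_id %in% cohort$patient_id, ]
  day <- as.numeric(mc$start_date) - idx[mc$patient_id]
  mc <- mc[day >= lo & day < hi, ]

  ph <- bundle$pharmacy_claims
  ph <- ph[ph$patient_id %in% cohort$patient_id, ]
  pday <- as.numeric(ph$dispense_date) - idx[ph$patient_id]
  ph <- ph[pday >= lo & pday < hi, ]

  acc <- function(ids, val) {
    out <- stats::setNames(rep(0, nrow(cohort)), cohort$patient_id)
    if (length(ids)) {
      agg <- tapply(val, ids, sum)
      out[names(agg)] <- agg
    }
    out
  }
  inp <- mc$setting == "inpatient"
  outp <- mc$setting == "outpatient"
  ed <- mc$setting == "ED"
  hosp_days <- pmax(1, as.numeric(mc$end_date) - as.numeric(mc$start_date))

  tibble::tibble(
    patient_id = cohort$patient_id,
    admissions = unname(acc(mc$patient_id[inp], rep(1, sum(inp)))),
    hospital_days = unname(acc(mc$patient_id[inp], hosp_days[inp])),
    ed_visits = unname(acc(mc$patient_id[ed], rep(1, sum(ed)))),
    outpatient_visits = unname(acc(mc$patient_id[outp], rep(1, sum(outp)))),
    inpatient_ntd = unname(acc(mc$patient_id[inp], mc$nonmedication_cost_ntd[inp])),
    outpatient_ntd = unname(acc(mc$patient_id[outp], mc$nonmedication_cost_ntd[outp])),
    ed_ntd = unname(acc(mc$patient_id[ed], mc$nonmedication_cost_ntd[ed])),
    medication_ntd = unname(acc(mc$patient_id, mc$medication_cost_ntd)) +
      unname(acc(ph$patient_id, ph$cost_ntd))
  ) |>
    dplyr::mutate(total_ntd = .data$inpatient_ntd + .data$outpatient_ntd +
      .data$ed_ntd + .data$medication_ntd)
}

#' Extract switch records
#'
#' A patient switches at the first dispense of a non-index bDMARD agent
#' within the horizon (default three years).
#'
#' @param cohort Cohort tibble.
#' @param bundle A [claims_bundle()].
#' @param horizon_days Switch detection horizon in days from index.
#' @return A tibble: `patient_id`, `from_agent`, `to_agent`, `switch_day`.
#' @export
extract_switches <- function(cohort, bundle, horizon_days = 1095L) {
  ph <- bundle$pharmacy_claims
  ph <- ph[ph$drug_class == "bDMARD" & ph$patient_id %in% cohort$patient_id, ]
  ph <- dplyr::left_join(
    ph[c("patient_id", "dispense_date", "bdmard_agent")],
    cohort[c("patient_id", "index_date", "index_agent")],
    by = "patient_id"
  )
  ph$day <- as.numeric(ph$dispense_date) - as.numeric(ph$index_date)
  ph <- ph[ph$bdmard_agent != ph$index_agent & ph$day >= 0 & ph$day < horizon_days, ]
  if (nrow(ph) == 0) {
    return(tibble::tibble(
      patient_id = character(0), from_agent = character(0),
      to_agent = character(0), switch_day = numeric(0)
    ))
  }
  ph |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      from_agent = .data$index_agent,
      to_agent = .data$bdmard_agent,
      switch_day = .data$day
    )
}

#' Mean time to switch among switchers
#'
#' Conditional means: only patients who switched contribute; agents with no
#' switchers are absent from the result rather than reported as zero.
#'
#' @param switches Tibble from [extract_switches()].
#' @return A tibble: `from_agent`, `n`, `mean_days`, `sd_days`.
#' @export
time_to_switch <- function(switches) {
  if (nrow(switches) == 0) {
    return(tibble::tibble(
      from_agent = character(0), n = integer(0),
      mean_days = numeric(0), sd_days = numeric(0)
    ))
  }
  switches |>
    dplyr::group_by(from_agent = .data$from_agent) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_days = mean(.data$switch_day),
      sd_days = stats::sd(.data$switch_day),
      .groups = "drop"
    )
}

#' Switch destination matrix
#'
#' Destination counts per index agent with row percentages of that agent's
#' switchers, rounded half-up to whole percent.
#'
#' @param switches Tibble from [extract_switches()].
#' @return A tibble: `from_agent`, `to_agent`, `n`, `pct`.
#' @export
switch_matrix <- function(switches) {
  if (nrow(switches) == 0) {
    return(tibble::tibble(
      from_agent = character(0), to_agent = character(0),
      n = integer(0), pct = numeric(0)
    ))
  }
  switches |>
    dplyr::count(.data$from_agent, .data$to_agent, name = "n") |>
    dplyr::group_by(.data$from_agent) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$from_agent, dplyr::desc(.data$n))
}

#' Assemble the full report
#'
#' Builds the table analogues the analysis prints: baseline characteristics
#' by response cohort, annual resource use and direct costs for three
#' follow-up years, the attrition table, the switch matrix, conditional time
#' to switch, criterion attribution, and derived cells (non-medication
#' subtotals and the medication share of total costs) computed from
#' components.
#'
#' @param cohort,attrition Output of [build_cohort()].
#' @param results Classification tibble from [classify_response()].
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()].
#' @return A named list of tibbles.
#' @export
build_report <- function(cohort, attrition, results, bundle,
                         config = study_config()) {
  cohort <- cohort_cci(cohort, bundle, config)
  status <- stats::setNames(results$status, results$patient_id)[cohort$patient_id]
  base_groups <- c(
    list(all = rep(TRUE, nrow(cohort))),
    lapply(c(Stable = "Stable", IR = "IR", Unknown = "Unknown"), function(s) status == s)
  )
  baseline <- purrr::map_dfr(names(base_groups), function(g) {
    sub <- cohort[base_groups[[g]], ]
    tibble::tibble(
      cohort = g, n = nrow(sub),
      age_mean = mean(sub$age_at_index), age_sd = stats::sd(sub$age_at_index),
      n_female = sum(sub$sex == "female"),
      pct_female = if (nrow(sub)) round_half_up(100 * sum(sub$sex == "female") / nrow(sub)) else NA_real_,
      cci_mean = mean(sub$cci), cci_sd = stats::sd(sub$cci)
    )
  })

  hcru_costs <- purrr::map_dfr(1:3, function(k) {
    summarize_year(cohort, results, bundle, config, year = k)
  })
  derived <- hcru_costs |>
    dplyr::transmute(
      cohort = .data$cohort, year = .data$year,
      nonmedication_usd_mean = convert_currency(
        .data$inpatient_ntd_mean + .data$outpatient_ntd_mean + .data$ed_ntd_mean,
        config$exchange_rate_usd_per_ntd
      ),
      medication_share_pct = round_half_up(
        100 * .data$medication_ntd_mean / .data$total_ntd_mean
      )
    )

  switches <- extract_switches(cohort, bundle)
  list(
    baseline = baseline,
    attrition = attrition,
    attribution = attribute_criteria(results),
    hcru_costs = hcru_costs,
    derived = derived,
    switches = switches,
    switch_matrix = switch_matrix(switches),
    time_to_switch = time_to_switch(switches)
  )
}

#' Write report tables to a directory
#'
#' One CSV per table plus a plain-text summary.
#'
#' @param report List from [build_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  for (nm in names(report)) {
    readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines("Claims-based bDMARD response analysis", con)
  writeLines(sprintf("Cohort size: %d", report$baseline$n[report$baseline$cohort == "all"]), con)
  for (nm in c("baseline", "attribution", "time_to_switch")) {
    writeLines(c("", paste0("== ", nm, " ==")), con)
    writeLines(utils::capture.output(print(as.data.frame(report[[nm]]))), con)
  }
  invisible(dir)
}
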