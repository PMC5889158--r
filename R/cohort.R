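#' Continuous-enrollment check
#'
#' A patient is continuously enrolled over a window when the union of
#' coverage intervals spans it with every gap (leading, internal or trailing)
#' strictly shorter than the tolerance. A gap of exactly `tolerance_days`
#' counts as a break, matching the convention that breaks of under 30 days
#' are ignored.
#'
#' @param coverage Data frame with `coverage_start`, `coverage_end` (closed
#'   date intervals) for one patient.
#' @param window_start,window_end Window as a half-open date interval
#'   `[window_start, window_end)`.
#' @param tolerance_days Integer; gaps `< tolerance_days` are bridged.
#' @return `TRUE` or `FALSE`.
#' @export
check_continuous_enrollment <- function(coverage, window_start, window_end,
                                        tolerance_days = 30L) {
  w_lo <- as.numeric(as.Date(window_start))
  w_hi <- as.numeric(as.Date(window_end)) - 1 # last day that must be covered
  if (w_hi < w_lo) {
    return(TRUE)
  }
  if (nrow(coverage) == 0) {
    return(FALSE)
  }
  s <- pmax(as.numeric(coverage$coverage_start), w_lo)
  e <- pmin(as.numeric(coverage$coverage_end), w_hi)
  keep <- e >= s
  if (!any(keep)) {
    return(FALSE)
  }
  merged <- merge_intervals(s[keep], e[keep], tolerance = tolerance_days)
  # leading / trailing uncovered runs are gaps too
  any(merged$start - w_lo < tolerance_days &
    w_hi - merged$end < tolerance_days &
    w_hi >= merged$start & w_lo <= merged$end)
}

#' Find candidate index events
#'
#' A patient's index event is their first-ever bDMARD dispense over all
#' available history, retained only when it falls inside the index period
#' (new-user design: any earlier bDMARD dispense disqualifies the patient).
#' Patients dispensed two distinct agents on the index date have no
#' principled index agent and are excluded as ambiguous.
#'
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()].
#' @return A list: `events` (tibble `patient_id`, `index_date`,
#'   `index_agent`), `n_bdmard_users` (patients with any bDMARD claim) and
#'   `ambiguous` (excluded patient ids).
#' @export
find_index_events <- function(bundle, config = study_config()) {
  ph <- bundle$pharmacy_claims
  bd <- ph[ph$drug_class == "bDMARD", c("patient_id", "dispense_date", "bdmard_agent")]
  if (nrow(bd) == 0) {
    return(list(
      events = tibble::tibble(
        patient_id = character(0),
        index_date = as.Date(character(0)), index_agent = character(0)
      ),
      n_bdmard_users = 0L, ambiguous = character(0)
    ))
  }
  first <- bd |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(.data$dispense_date == min(.data$dispense_date)) |>
    dplyr::summarise(
      index_date = .data$dispense_date[1],
      agents = list(sort(unique(.data$bdmard_agent))),
      .groups = "drop"
    )
  in_period <- first$index_date >= config$index_start & first$index_date <= config$index_end
  first <- first[in_period, ]
  n_agents <- lengths(first$agents)
  ambiguous <- first$patient_id[n_agents > 1]
  first <- first[n_agents == 1, ]
  list(
    events = tibble::tibble(
      patient_id = first$patient_id,
      index_date = first$index_date,
      index_agent = vapply(first$agents, `[[`, "", 1)
    ) |> dplyr::arrange(.data$patient_id),
    n_bdmard_users = dplyr::n_distinct(bd$patient_id),
    ambiguous = ambiguous
  )
}

#' @noRd
patients_with_code <- function(bundle, cl, from = NULL, to = NULL) {
  mc <- bundle$medical_claims
  if (!is.null(from)) {
    mc <- mc[mc$start_date >= from & mc$start_date <= to, ]
  }
  if (nrow(mc) == 0) {
    return(character(0))
  }
  codes <- strsplit(mc$diagnosis_codes, ";", fixed = TRUE)
  hit <- vapply(codes, function(cc) any(code_matches(cc, cl)), logical(1))
  unique(mc$patient_id[hit])
}

#' Apply inclusion rules
#'
#' Retains candidates with at least one healthcare event carrying an RA
#' diagnosis (714.xx excluding 714.3) and an RA catastrophic-illness
#' certification (by default effective on or before the index date).
#'
#' @param events Candidate events from [find_index_events()].
#' @param bundle A [claims_bundle()].
#' @param code_lists Named code lists, see [default_code_lists()].
#' @param config A [study_config()].
#' @return A list: `events` (retained) and `attrition` rows.
#' @export
apply_inclusion <- function(events, bundle, code_lists = default_code_lists(),
                            config = study_config()) {
  ra <- code_lists$RA_diagnosis
  with_ra <- patients_with_code(bundle, ra)
  keep_ra <- events$patient_id %in% with_ra
  att <- attrition_row("no RA diagnosis (714.xx excl. 714.3)", events, keep_ra)
  events <- events[keep_ra, ]

  ci <- bundle$catastrophic_illness
  ci <- ci[code_matches(ci$icd9_code, ra), ]
  if (config$require_card_before_index) {
    first_card <- tapply(ci$effective_date, ci$patient_id, min)
    keep_card <- !is.na(first_card[events$patient_id]) &
      as.Date(first_card[events$patient_id], origin = "1970-01-01") <= events$index_date
  } else {
    keep_card <- events$patient_id %in% ci$patient_id
  }
  keep_card[is.na(keep_card)] <- FALSE
  att <- dplyr::bind_rows(
    att,
    attrition_row("no RA catastrophic-illness certification", events, keep_card)
  )
  list(events = events[keep_card, ], attrition = att)
}

#' Apply exclusion rules
#'
#' The four exclusions in their printed order: age under 18 at index; not in
#' the database over the pre-index window (breaks under the tolerance
#' ignored); any claim for comorbid inflammatory conditions; any solid-tumor
#' or hematologic malignancy (140-208, non-melanoma skin cancer 173
#' carved out) or HIV/AIDS (042-044). Diagnosis scans for the last two cover
#' the entire study horizon.
#'
#' @inheritParams apply_inclusion
#' @return A list: `events` (the final cohort, with `age_at_index` and `sex`
#'   attached) and `attrition` rows.
#' @export
apply_exclusion <- function(events, bundle, code_lists = default_code_lists(),
                            config = study_config()) {
  en <- bundle$enrollment
  birth <- tapply(en$birth_date, en$patient_id, min)
  age <- completed_years(
    as.Date(birth[events$patient_id], origin = "1970-01-01"),
    events$index_date
  )
  keep <- !is.na(age) & age >= 18
  att <- attrition_row("aged <18 years at index", events, keep)
  events <- events[keep, ]
  age <- age[keep]

  cov_by_pt <- split(en[c("coverage_start", "coverage_end")], en$patient_id)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    cov <- cov_by_pt[[events$patient_id[i]]]
    !is.null(cov) && check_continuous_enrollment(
      cov,
      events$index_date[i] - config$pre_index_days, events$index_date[i],
      config$enrollment_gap_tolerance_days
    )
  }, logical(1))
  att <- dplyr::bind_rows(
    att,
    attrition_row("not enrolled over the pre-index period", events, keep)
  )
  events <- events[keep, ]
  age <- age[keep]

  infl <- patients_with_code(
    bundle, code_lists$exclusion_inflammatory,
    config$study_start, config$study_end
  )
  keep <- !(events$patient_id %in% infl)
  att <- dplyr::bind_rows(
    att,
    attrition_row("comorbid inflammatory condition", events, keep)
  )
  events <- events[keep, ]
  age <- age[keep]

  malig <- patients_with_code(
    bundle, code_lists$exclusion_malignancy_hiv,
    config$study_start, config$study_end
  )
  keep <- !(events$patient_id %in% malig)
  att <- dplyr::bind_rows(
    att,
    attrition_row("malignancy or HIV/AIDS", events, keep)
  )
  events <- events[keep, ]
  age <- age[keep]

  sex <- tapply(en$sex, en$patient_id, `[[`, 1)
  events$age_at_index <- as.integer(age)
  events$sex <- unname(sex[events$patient_id])
  list(events = events, attrition = att)
}

#' @noRd
attrition_row <- function(rule, events, keep) {
  tibble::tibble(
    rule = rule,
    n_excluded = sum(!keep),
    n_remaining = sum(keep)
  )
}

# Age in completed years (birthday-based administrative convention).
#' @noRd
completed_years <- function(birth, at) {
  b <- as.POSIXlt(birth)
  a <- as.POSIXlt(at)
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  age - as.integer(before_birthday)
}

#' Build the new-user cohort
#'
#' Runs index-event detection, inclusion and exclusion in order and emits the
#' final cohort together with a full attrition table.
#'
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()].
#' @param code_lists Named code lists, see [default_code_lists()].
#' @return A list: `cohort` (tibble with `patient_id`, `index_date`,
#'   `index_agent`, `age_at_index`, `sex`) and `attrition` (tibble
#'   `rule`, `n_excluded`, `n_remaining`, monotone in `n_remaining`).
#' @export
build_cohort <- function(bundle, config = study_config(),
                         code_lists = default_code_lists()) {
  fe <- find_index_events(bundle, config)
  att <- tibble::tibble(
    rule = c(
      "any bDMARD dispense",
      "first-ever bDMARD dispense inside the index period",
      "unambiguous index agent"
    ),
    n_excluded = c(
      0L,
      fe$n_bdmard_users - nrow(fe$events) - length(fe$ambiguous),
      length(fe$ambiguous)
    ),
    n_remaining = c(
      fe$n_bdmard_users,
      nrow(fe$events) + length(fe$ambiguous),
      nrow(fe$events)
    )
  )
  inc <- apply_inclusion(fe$events, bundle, code_lists, config)
  exc <- apply_exclusion(inc$events, bundle, code_lists, config)
  list(
    cohort = exc$events,
    attrition = dplyr::bind_rows(att, inc$attrition, exc$attrition)
  )
}
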