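#' Default Deyo ICD-9-CM Charlson map
#'
#' The 17-category Deyo adaptation of the Charlson comorbidity index with the
#' widely used ICD-9-CM prefix lists and weights (1, 2, 3 or 6). Hierarchy
#' groups encode mild/severe pairs: within a group only the highest
#' `severity_rank` category triggered by a patient is scored (uncomplicated
#' diabetes is suppressed by diabetes with complications, mild liver disease
#' by moderate/severe liver disease, any malignancy by metastatic solid
#' tumor).
#'
#' @return A tibble with columns `category`, `icd9_prefix`, `weight`,
#'   `hierarchy_group`, `severity_rank` (one row per prefix).
#' @export
default_charlson_map <- function() {
  spec <- list(
    list("myocardial_infarction", c("410", "412"), 1, NA, NA),
    list("congestive_heart_failure", "428", 1, NA, NA),
    list("peripheral_vascular_disease", c("441", "4439", "7854", "V434"), 1, NA, NA),
    list("cerebrovascular_disease", sprintf("%03d", 430:438), 1, NA, NA),
    list("dementia", "290", 1, NA, NA),
    list("chronic_pulmonary_disease", c(sprintf("%03d", c(490:496, 500:505)), "5064"), 1, NA, NA),
    list("rheumatic_disease", c("7100", "7101", "7104", "7140", "7141", "7142", "71481", "725"), 1, NA, NA),
    list("peptic_ulcer_disease", sprintf("%03d", 531:534), 1, NA, NA),
    list("mild_liver_disease", c("5712", "5714", "5715", "5716"), 1, "liver", 1),
    list("diabetes", c("2500", "2501", "2502", "2503", "2507"), 1, "diabetes", 1),
    list("diabetes_with_complications", c("2504", "2505", "2506"), 2, "diabetes", 2),
    list("hemiplegia_paraplegia", c("342", "3441"), 2, NA, NA),
    list("renal_disease", c("582", sprintf("583%d", 0:7), "585", "586", "588"), 2, NA, NA),
    list("malignancy", sprintf("%03d", c(140:172, 174:195, 200:208)), 2, "cancer", 1),
    list("moderate_severe_liver_disease", c("4560", "4561", "4562", "5722", "5723", "5724", "5728"), 3, "liver", 2),
    list("metastatic_solid_tumor", sprintf("%03d", 196:199), 6, "cancer", 2),
    list("aids_hiv", c("042", "043", "044"), 6, NA, NA)
  )
  purrr::map_dfr(spec, function(s) {
    tibble::tibble(
      category = s[[1]], icd9_prefix = s[[2]], weight = as.integer(s[[3]]),
      hierarchy_group = as.character(s[[4]]), severity_rank = as.integer(s[[5]])
    )
  })
}

#' Load a Charlson map from a delimited file
#'
#' @param path CSV with the columns of [default_charlson_map()].
#' @return A validated map tibble.
#' @export
load_charlson_map <- function(path) {
  map <- readr::read_csv(path,
    col_types = readr::cols(
      category = readr::col_character(),
      icd9_prefix = readr::col_character(),
      weight = readr::col_integer(),
      hierarchy_group = readr::col_character(),
      severity_rank = readr::col_integer()
    ),
    progress = FALSE
  )
  if (!all(map$weight %in% c(1L, 2L, 3L, 6L))) {
    abort_claimsir("Charlson weights must be 1, 2, 3 or 6.", "claimsir_codelist_error")
  }
  map$icd9_prefix <- normalize_code(map$icd9_prefix)
  map
}

#' Charlson comorbidity score for one set of diagnosis codes
#'
#' Prefix-matches the codes against the map, applies hierarchy suppression
#' and sums the weights of triggered categories.
#'
#' @param codes Character vector of ICD-9-CM codes (any recorded precision).
#' @param map Charlson map tibble, see [default_charlson_map()].
#' @param count_rheumatic Include the rheumatic-disease category (every RA
#'   patient carries it) in the score?
#' @return A list: `score` (integer) and `categories` (character vector of
#'   scored categories).
#' @export
#' @examples
#' compute_cci(c("714.0", "250.0")) # RA + uncomplicated diabetes: score 2
compute_cci <- function(codes, map = default_charlson_map(), count_rheumatic = TRUE) {
  codes <- unique(normalize_code(codes))
  hit <- vapply(
    split(map$icd9_prefix, map$category)[unique(map$category)],
    function(prefixes) any(match_entries(codes, prefixes, "prefix")),
    logical(1)
  )
  cats <- map[!duplicated(map$category), c("category", "weight", "hierarchy_group", "severity_rank")]
  cats <- cats[hit[cats$category], , drop = FALSE]
  if (!count_rheumatic) {
    cats <- cats[cats$category != "rheumatic_disease", , drop = FALSE]
  }
  # hierarchy suppression: keep only the most severe triggered member per group
  grouped <- !is.na(cats$hierarchy_group)
  if (any(grouped)) {
    keep <- rep(TRUE, nrow(cats))
    for (g in unique(cats$hierarchy_group[grouped])) {
      idx <- which(!is.na(cats$hierarchy_group) & cats$hierarchy_group == g)
      if (length(idx) > 1) {
        keep[idx[-which.max(cats$severity_rank[idx])]] <- FALSE
      }
    }
    cats <- cats[keep, , drop = FALSE]
  }
  list(score = as.integer(sum(cats$weight)), categories = cats$category)
}

#' Baseline Charlson score for every cohort patient
#'
#' Scans each patient's medical-claim diagnoses in the lookback window (the
#' pre-index window plus the index date; one claim in any setting suffices)
#' and returns the Deyo-weighted score.
#'
#' @param cohort Cohort tibble from [build_cohort()] (needs `patient_id`,
#'   `index_date`).
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()]; supplies the lookback length and the
#'   `cci_count_rheumatic` switch.
#' @param map Charlson map tibble.
#' @return `cohort` with an added integer column `cci`.
#' @export
cohort_cci <- function(cohort, bundle, config = study_config(),
                       map = default_charlson_map()) {
  mc <- bundle$medical_claims
  mc <- mc[mc$patient_id %in% cohort$patient_id, c("patient_id", "start_date", "diagnosis_codes")]
  idx <- stats::setNames(cohort$index_date, cohort$patient_id)
  lo <- idx[mc$patient_id] - config$pre_index_days
  hi <- idx[mc$patient_id] # lookback includes the index date
  mc <- mc[mc$start_date >= lo & mc$start_date <= hi, ]
  dx_by_pt <- split(mc$diagnosis_codes, mc$patient_id)
  cohort$cci <- vapply(cohort$patient_id, function(pid) {
    codes <- unlist(strsplit(dx_by_pt[[pid]] %||% character(0), ";", fixed = TRUE))
    compute_cci(codes, map, count_rheumatic = config$cci_count_rheumatic)$score
  }, integer(1), USE.NAMES = FALSE)
  cohort
}
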