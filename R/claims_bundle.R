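#' @noRd
SETTINGS <- c("outpatient", "inpatient", "ED")

#' Biologic DMARD agents in scope
#'
#' The five agents reimbursed for RA in Taiwan during the study horizon.
#' @export
BDMARD_AGENTS <- c("abatacept", "adalimumab", "etanercept", "golimumab", "tocilizumab")

#' @noRd
DRUG_CLASSES <- c("bDMARD", "csDMARD", "oral_GC", "injectable_GC", "NSAID", "other")

#' @noRd
table_schemas <- function() {
  list(
    enrollment = c(
      patient_id = "c", birth_date = "D", sex = "c",
      coverage_start = "D", coverage_end = "D", death_date = "D"
    ),
    catastrophic_illness = c(
      patient_id = "c", icd9_code = "c", effective_date = "D"
    ),
    medical_claims = c(
      patient_id = "c", setting = "c", start_date = "D", end_date = "D",
      diagnosis_codes = "c", is_gc_joint_injection = "l",
      medication_cost_ntd = "d", nonmedication_cost_ntd = "d"
    ),
    pharmacy_claims = c(
      patient_id = "c", dispense_date = "D", drug_code = "c",
      drug_class = "c", bdmard_agent = "c", days_supplied = "i",
      prednisone_equivalent_mg_total = "d", cost_ntd = "d"
    )
  )
}

#' @noRd
empty_table <- function(schema) {
  cols <- lapply(schema, function(tt) {
    switch(tt,
      c = character(0),
      D = as.Date(character(0)),
      l = logical(0),
      i = integer(0),
      d = numeric(0)
    )
  })
  tibble::as_tibble(cols)
}

#' Construct and validate a claims bundle
#'
#' A claims bundle holds the four claim tables every pipeline stage consumes:
#' enrollment (one row per coverage interval), the catastrophic-illness
#' registry, medical claims (one row per encounter, diagnosis codes packed as
#' a semicolon-separated string) and pharmacy claims (one row per dispensing).
#' Construction validates every schema and row-level invariant; malformed
#' input raises a classed error rather than being silently dropped.
#'
#' @param enrollment,catastrophic_illness,medical_claims,pharmacy_claims
#'   Data frames following the documented schemas (see
#'   `vignette("claims-ir-pipeline")`). Missing arguments default to empty
#'   tables.
#' @return A list of class `claims_bundle`.
#' @export
claims_bundle <- function(enrollment = NULL, catastrophic_illness = NULL,
                          medical_claims = NULL, pharmacy_claims = NULL) {
  schemas <- table_schemas()
  tabs <- list(
    enrollment = enrollment,
    catastrophic_illness = catastrophic_illness,
    medical_claims = medical_claims,
    pharmacy_claims = pharmacy_claims
  )
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) {
      tabs[[nm]] <- empty_table(schemas[[nm]])
    } else {
      tabs[[nm]] <- coerce_table(tabs[[nm]], schemas[[nm]], nm)
    }
  }
  bundle <- structure(tabs, class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %7d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' @noRd
coerce_table <- function(df, schema, table_name) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    abort_claimsir(
      sprintf(
        "Table '%s' is missing column(s): %s",
        table_name, paste(missing, collapse = ", ")
      ),
      "claimsir_schema_error"
    )
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      c = as.character(df[[col]]),
      D = coerce_date(df[[col]], table_name, col),
      l = as.logical(df[[col]]),
      i = as.integer(df[[col]]),
      d = as.numeric(df[[col]])
    )
  }
  df
}

#' @noRd
coerce_date <- function(x, table_name, col) {
  if (inherits(x, "Date")) {
    return(x)
  }
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & nzchar(as.character(x)) & is.na(out))
  if (length(bad)) {
    abort_claimsir(
      sprintf(
        "Table '%s', column '%s': unparseable date at data row(s) %s (ISO-8601 expected).",
        table_name, col, paste(utils::head(bad, 5), collapse = ", ")
      ),
      "claimsir_parse_error"
    )
  }
  out
}

#' @noRd
fail_rows <- function(bad, table_name, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    abort_claimsir(
      sprintf(
        "Table '%s': %s (row(s) %s%s).",
        table_name, what, paste(utils::head(rows, 5), collapse = ", "),
        if (length(rows) > 5) ", ..." else ""
      ),
      "claimsir_invariant_error"
    )
  }
}

#' @noRd
check_enum <- function(x, allowed, table_name, col) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (any(bad)) {
    abort_claimsir(
      sprintf(
        "Table '%s', column '%s': unknown value(s) %s; allowed: %s.",
        table_name, col,
        paste(sQuote(utils::head(unique(x[bad]), 5)), collapse = ", "),
        paste(allowed, collapse = ", ")
      ),
      "claimsir_invariant_error"
    )
  }
}

#' @noRd
validate_bundle <- function(b) {
  en <- b$enrollment
  check_enum(en$sex, c("male", "female"), "enrollment", "sex")
  fail_rows(is.na(en$patient_id) | !nzchar(en$patient_id), "enrollment", "empty patient_id")
  fail_rows(en$coverage_end < en$coverage_start, "enrollment", "coverage interval ends before it starts")
  fail_rows(!is.na(en$death_date) & en$death_date < en$birth_date,
    "enrollment", "death_date precedes birth_date")
  if (nrow(en) > 1) {
    sp <- split(seq_len(nrow(en)), en$patient_id)
    for (rows in sp) {
      if (length(rows) > 1) {
        o <- order(en$coverage_start[rows])
        s <- en$coverage_start[rows][o]
        e <- en$coverage_end[rows][o]
        if (any(s[-1] <= e[-length(e)])) {
          abort_claimsir(
            sprintf(
              "Table 'enrollment': overlapping or unsorted coverage intervals for patient %s.",
              en$patient_id[rows[1]]
            ),
            "claimsir_invariant_error"
          )
        }
      }
    }
  }

  ci <- b$catastrophic_illness
  fail_rows(is.na(ci$icd9_code) | !nzchar(ci$icd9_code), "catastrophic_illness", "empty icd9_code")

  mc <- b$medical_claims
  check_enum(mc$setting, SETTINGS, "medical_claims", "setting")
  fail_rows(is.na(mc$diagnosis_codes) | !nzchar(mc$diagnosis_codes),
    "medical_claims", "claim with no diagnosis codes")
  fail_rows(mc$setting != "inpatient" & mc$end_date != mc$start_date,
    "medical_claims", "outpatient/ED claim whose end_date differs from start_date")
  fail_rows(mc$end_date < mc$start_date, "medical_claims", "end_date before start_date")
  fail_rows(!is.finite(mc$medication_cost_ntd) | mc$medication_cost_ntd < 0 |
    !is.finite(mc$nonmedication_cost_ntd) | mc$nonmedication_cost_ntd < 0,
  "medical_claims", "negative or non-finite cost")
  fail_rows(is.na(mc$is_gc_joint_injection), "medical_claims", "missing is_gc_joint_injection flag")

  ph <- b$pharmacy_claims
  check_enum(ph$drug_class, DRUG_CLASSES, "pharmacy_claims", "drug_class")
  check_enum(ph$bdmard_agent, BDMARD_AGENTS, "pharmacy_claims", "bdmard_agent")
  fail_rows(is.na(ph$days_supplied) | ph$days_supplied < 1, "pharmacy_claims",
    "days_supplied below 1")
  fail_rows(!is.finite(ph$cost_ntd) | ph$cost_ntd < 0, "pharmacy_claims",
    "negative or non-finite cost")
  fail_rows(ph$drug_class == "bDMARD" & is.na(ph$bdmard_agent), "pharmacy_claims",
    "bDMARD dispense without bdmard_agent")
  fail_rows(ph$drug_class != "bDMARD" & !is.na(ph$bdmard_agent), "pharmacy_claims",
    "bdmard_agent set on a non-bDMARD dispense")
  fail_rows(ph$drug_class == "oral_GC" &
    (is.na(ph$prednisone_equivalent_mg_total) | ph$prednisone_equivalent_mg_total < 0),
  "pharmacy_claims", "oral_GC dispense without a valid prednisone_equivalent_mg_total")
  fail_rows(ph$drug_class != "oral_GC" & !is.na(ph$prednisone_equivalent_mg_total),
    "pharmacy_claims", "prednisone_equivalent_mg_total set on a non-oral_GC dispense")
  invisible(b)
}

#' Write a claims bundle as delimited text
#'
#' Four comma-delimited UTF-8 files with header rows, ISO-8601 dates and a
#' stable column order; repeated calls on the same bundle are byte-identical.
#'
#' @param bundle A [claims_bundle()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_claims_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- vapply(names(bundle), function(nm) file.path(dir, paste0(nm, ".csv")), "")
  for (nm in names(bundle)) {
    readr::write_csv(bundle[[nm]], paths[[nm]], na = "", progress = FALSE)
  }
  invisible(paths)
}

#' Read a claims bundle from delimited text
#'
#' The inverse of [write_claims_tables()]: reads, type-coerces and validates
#' the four tables. `read_claims_tables(write_claims_tables(b)) == b` for any
#' valid bundle.
#'
#' @param dir Directory containing `enrollment.csv`,
#'   `catastrophic_illness.csv`, `medical_claims.csv`, `pharmacy_claims.csv`;
#'   alternatively a named character vector of explicit file paths.
#' @return A validated [claims_bundle()].
#' @export
read_claims_tables <- function(dir) {
  nms <- names(table_schemas())
  paths <- if (length(dir) == 1 && is.null(names(dir))) {
    stats::setNames(file.path(dir, paste0(nms, ".csv")), nms)
  } else {
    dir
  }
  missing <- nms[!file.exists(paths[nms])]
  if (length(missing)) {
    abort_claimsir(
      sprintf("Missing claim table file(s): %s", paste(paths[missing], collapse = ", ")),
      "claimsir_io_error"
    )
  }
  tabs <- lapply(nms, function(nm) {
    readr::read_csv(paths[[nm]],
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, na = c("", "NA")
    )
  })
  names(tabs) <- nms
  do.call(claims_bundle, tabs)
}
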