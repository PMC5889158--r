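#' Oral glucocorticoid prednisone-equivalence table
#'
#' Standard potency conversions: the returned factor turns a drug's
#' milligrams into prednisone-equivalent milligrams (e.g. 4 mg
#' methylprednisolone is equipotent with 5 mg prednisone, factor 1.25).
#'
#' @return A tibble: `drug_code`, `drug_name`, `equivalent_mg` (dose
#'   equipotent with 5 mg prednisone) and `factor`.
#' @export
gc_equivalence <- function() {
  tibble::tibble(
    drug_code = c("PRED", "PREDL", "MPRED", "DEXA", "HCORT"),
    drug_name = c(
      "prednisone", "prednisolone", "methylprednisolone",
      "dexamethasone", "hydrocortisone"
    ),
    equivalent_mg = c(5, 5, 4, 0.75, 20),
    factor = 5 / c(5, 5, 4, 0.75, 20)
  )
}

#' Convert an oral glucocorticoid amount to prednisone equivalents
#'
#' @param drug_code Drug codes present in [gc_equivalence()].
#' @param mg Total milligrams of the drug.
#' @return Prednisone-equivalent milligrams.
#' @export
#' @examples
#' prednisone_equivalents("MPRED", 600) # 750
prednisone_equivalents <- function(drug_code, mg) {
  eq <- gc_equivalence()
  f <- eq$factor[match(drug_code, eq$drug_code)]
  if (anyNA(f)) {
    abort_claimsir(
      sprintf(
        "Unknown glucocorticoid drug code(s): %s",
        paste(unique(drug_code[is.na(f)]), collapse = ", ")
      ),
      "claimsir_codelist_error"
    )
  }
  mg * f
}

#' Run the full pipeline on a synthetic scenario
#'
#' Generate, build the cohort, classify response and assemble the report in
#' one call.
#'
#' @param spec A [scenario_spec()], e.g. [taiwan_2010_preset()].
#' @param config A [study_config()].
#' @param code_lists Named code lists.
#' @return A list: `bundle`, `truth`, `cohort`, `attrition`, `results`,
#'   `report`.
#' @export
run_pipeline <- function(spec, config = study_config(),
                         code_lists = default_code_lists()) {
  gen <- generate_claims(spec, config)
  built <- build_cohort(gen$bundle, config, code_lists)
  results <- classify_response(built$cohort, gen$bundle, config)
  report <- build_report(built$cohort, built$attrition, results, gen$bundle, config)
  list(
    bundle = gen$bundle, truth = gen$truth,
    cohort = built$cohort, attrition = built$attrition,
    results = results, report = report
  )
}
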