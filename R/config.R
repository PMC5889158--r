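#' Study configuration
#'
#' Bundles every tunable window and threshold of the pipeline. Defaults
#' reproduce the published Taiwan analysis rules: a 2010 index period with
#' 365-day pre-index and follow-up windows, a strict 0.80
#' proportion-of-days-covered threshold, "more than one" glucocorticoid joint
#' injection, a strict (0% margin) oral-glucocorticoid dose increase assessed
#' after a 90-day bridging exclusion, enrollment breaks under 30 days
#' ignored, and NT$-to-USD conversion at 0.033.
#'
#' @param index_start,index_end Index period bounds (dates, inclusive).
#' @param pre_index_days,follow_up_days Window lengths in days.
#' @param pdc_threshold PDC below which adherence is inadequate (strict `<`).
#' @param gc_injection_min_count Joint injections needed to flag criterion 4.
#'   Default 2 ("more than one"); set 1 for the at-least-one reading.
#' @param gc_increase_margin_pct Percent margin the follow-up mean daily oral
#'   glucocorticoid dose must exceed the pre-index mean by (0 = any increase).
#' @param gc_bridging_exclusion_days Days after index excluded from the
#'   oral-glucocorticoid comparison window (bridging steroids at biologic
#'   start are routine).
#' @param enrollment_gap_tolerance_days Coverage breaks strictly shorter than
#'   this are ignored; a gap of exactly this length counts as a break.
#' @param exchange_rate_usd_per_ntd USD per NT$.
#' @param study_start,study_end Full data horizon; exclusion-diagnosis scans
#'   cover this entire range.
#' @param require_card_before_index Must the catastrophic-illness RA
#'   certification predate (or equal) the index date?
#' @param cci_count_rheumatic Should the Charlson rheumatic-disease category
#'   (which every RA patient triggers) contribute to the score?
#' @param rng_seed Integer seed recorded alongside the configuration.
#' @return A list of class `study_config`.
#' @export
study_config <- function(index_start = as.Date("2010-01-01"),
                         index_end = as.Date("2010-12-31"),
                         pre_index_days = 365L,
                         follow_up_days = 365L,
                         pdc_threshold = 0.80,
                         gc_injection_min_count = 2L,
                         gc_increase_margin_pct = 0,
                         gc_bridging_exclusion_days = 90L,
                         enrollment_gap_tolerance_days = 30L,
                         exchange_rate_usd_per_ntd = 0.033,
                         study_start = as.Date("2009-01-01"),
                         study_end = as.Date("2013-12-31"),
                         require_card_before_index = TRUE,
                         cci_count_rheumatic = TRUE,
                         rng_seed = 1L) {
  cfg <- list(
    index_start = as.Date(index_start),
    index_end = as.Date(index_end),
    pre_index_days = as.integer(pre_index_days),
    follow_up_days = as.integer(follow_up_days),
    pdc_threshold = pdc_threshold,
    gc_injection_min_count = as.integer(gc_injection_min_count),
    gc_increase_margin_pct = gc_increase_margin_pct,
    gc_bridging_exclusion_days = as.integer(gc_bridging_exclusion_days),
    enrollment_gap_tolerance_days = as.integer(enrollment_gap_tolerance_days),
    exchange_rate_usd_per_ntd = exchange_rate_usd_per_ntd,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    require_card_before_index = isTRUE(require_card_before_index),
    cci_count_rheumatic = isTRUE(cci_count_rheumatic),
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$index_end < cfg$index_start) {
    abort_claimsir("index_end precedes index_start.", "claimsir_config_error")
  }
  if (cfg$pre_index_days < 1 || cfg$follow_up_days < 1) {
    abort_claimsir("Window lengths must be positive.", "claimsir_config_error")
  }
  if (!(cfg$pdc_threshold > 0 && cfg$pdc_threshold <= 1)) {
    abort_claimsir("pdc_threshold must lie in (0, 1].", "claimsir_config_error")
  }
  if (cfg$gc_increase_margin_pct < 0 || cfg$exchange_rate_usd_per_ntd <= 0) {
    abort_claimsir("Margins and exchange rate must be non-negative / positive.",
      "claimsir_config_error")
  }
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-30s %s\n", nm, as.character(x[[nm]])))
  }
  invisible(x)
}

#' Write a study configuration as a flat key=value file
#'
#' @param config A [study_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  lines <- vapply(
    names(config),
    function(nm) sprintf("%s=%s", nm, as.character(config[[nm]])),
    ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a study configuration from a flat key=value file
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path File written by [write_study_config()] (or by hand).
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  defaults <- study_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    abort_claimsir(
      sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
      "claimsir_config_error"
    )
  }
  args <- stats::setNames(as.list(vals), keys)
  for (nm in names(args)) {
    proto <- defaults[[nm]]
    args[[nm]] <- if (inherits(proto, "Date")) {
      as.Date(args[[nm]])
    } else if (is.logical(proto)) {
      as.logical(args[[nm]])
    } else if (is.integer(proto)) {
      as.integer(args[[nm]])
    } else {
      as.numeric(args[[nm]])
    }
  }
  do.call(study_config, args)
}
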