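#' Diagnosis and drug code lists
#'
#' A code list is a named set of ICD-9-CM prefixes (or exact drug codes)
#' together with optional carve-out entries. Claims codes are compared after
#' normalization (uppercase, dots stripped), so the common "714.xx" wildcard
#' notation becomes the prefix `"714"`, and a carve-out such as "excluding
#' 714.3" becomes the negative prefix `"7143"`. A code matches the list when
#' it matches at least one include entry and no exclude entry.
#'
#' @param name List name (unique within a set).
#' @param include Character vector of prefixes / exact codes. Must be
#'   non-empty.
#' @param exclude Optional carve-out entries, same notation.
#' @param match_rule `"prefix"` (default, ICD-9-CM style) or `"exact"` (drug
#'   codes).
#' @return An object of class `code_list`.
#' @export
#' @examples
#' ra <- code_list("RA_diagnosis", include = "714", exclude = "714.3")
#' code_matches(c("714.0", "714.3", "720.0"), ra) # TRUE FALSE FALSE
code_list <- function(name, include, exclude = character(),
                      match_rule = c("prefix", "exact")) {
  match_rule <- match.arg(match_rule)
  include <- normalize_code(include)
  exclude <- normalize_code(exclude)
  if (length(include) == 0 || any(!nzchar(include))) {
    abort_claimsir(
      sprintf("Code list '%s' must have at least one non-empty include entry.", name),
      "claimsir_codelist_error"
    )
  }
  structure(
    list(
      name = name, include = unique(include),
      exclude = unique(exclude), match_rule = match_rule
    ),
    class = "code_list"
  )
}

#' @export
print.code_list <- function(x, ...) {
  cat(
    sprintf(
      "<code_list> %s: %d include, %d exclude entries (%s match)\n",
      x$name, length(x$include), length(x$exclude), x$match_rule
    )
  )
  invisible(x)
}

#' Normalize an ICD-9-CM or drug code for comparison
#'
#' Uppercases and strips dots, whitespace and trailing "x" wildcard markers.
#'
#' @param x Character vector of codes.
#' @return Normalized character vector.
#' @export
normalize_code <- function(x) {
  x <- toupper(gsub("[. ]", "", as.character(x)))
  sub("X+$", "", x)
}

#' Test codes against a code list
#'
#' @param codes Character vector of raw codes (normalized internally).
#' @param cl A [code_list()].
#' @return Logical vector, one element per code.
#' @export
code_matches <- function(codes, cl) {
  stopifnot(inherits(cl, "code_list"))
  codes <- normalize_code(codes)
  hit <- match_entries(codes, cl$include, cl$match_rule)
  if (length(cl$exclude)) {
    hit <- hit & !match_entries(codes, cl$exclude, cl$match_rule)
  }
  hit
}

#' @noRd
match_entries <- function(codes, entries, match_rule) {
  if (length(entries) == 0) {
    return(rep(FALSE, length(codes)))
  }
  if (match_rule == "exact") {
    return(codes %in% entries)
  }
  out <- rep(FALSE, length(codes))
  for (e in entries) {
    out <- out | startsWith(codes, e)
  }
  out
}

#' Default diagnosis and drug code lists
#'
#' The lists needed by the cohort builder and downstream modules:
#' \describe{
#'   \item{RA_diagnosis}{ICD-9-CM 714.xx excluding juvenile chronic
#'     polyarthritis 714.3x.}
#'   \item{exclusion_inflammatory}{Psoriasis/psoriatic arthritis (696.xx),
#'     ankylosing spondylitis (720.0x), Crohn's disease (555.xx), ulcerative
#'     colitis (556.xx), juvenile chronic polyarthritis (714.3x).}
#'   \item{exclusion_malignancy_hiv}{Solid tumors and hematologic malignancy
#'     (three-digit prefixes 140-208, expanded at build time) excluding
#'     non-melanoma skin cancer (173.xx), plus HIV/AIDS (042.xx-044.xx).}
#'   \item{bdmard_agents, csdmard_agents, oral_gc_drugs}{Exact drug-code lists
#'     matching the codes emitted by the synthetic generator.}
#' }
#'
#' @return Named list of [code_list()] objects.
#' @export
default_code_lists <- function() {
  malignancy <- sprintf("%03d", 140:208)
  lists <- list(
    code_list("RA_diagnosis", include = "714", exclude = "7143"),
    code_list("exclusion_inflammatory",
      include = c("696", "7200", "555", "556", "7143")
    ),
    code_list("exclusion_malignancy_hiv",
      include = c(malignancy, "042", "043", "044"), exclude = "173"
    ),
    code_list("bdmard_agents",
      include = c("B-ABA", "B-ADA", "B-ETA", "B-GOL", "B-TOC"),
      match_rule = "exact"
    ),
    code_list("csdmard_agents",
      include = c("MTX", "HCQ", "SSZ", "LEF", "AZA", "CSA"),
      match_rule = "exact"
    ),
    code_list("oral_gc_drugs",
      include = c("PRED", "PREDL", "MPRED", "DEXA"), match_rule = "exact"
    )
  )
  stats::setNames(lists, vapply(lists, `[[`, "", "name"))
}

#' Write code lists to a delimited file
#'
#' One row per entry: `list_name, entry, role, match_rule` where `role` is
#' `include` or `exclude`. The file round-trips through [load_code_lists()].
#'
#' @param lists Named list of [code_list()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_code_lists <- function(lists, path) {
  rows <- purrr::map_dfr(lists, function(cl) {
    tibble::tibble(
      list_name = cl$name,
      entry = c(cl$include, cl$exclude),
      role = rep(c("include", "exclude"), c(length(cl$include), length(cl$exclude))),
      match_rule = cl$match_rule
    )
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' Load code lists from a delimited file
#'
#' @param path CSV with columns `list_name, entry, role, match_rule` (see
#'   [write_code_lists()]).
#' @return Named list of [code_list()] objects.
#' @export
load_code_lists <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("list_name", "entry", "role", "match_rule")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_claimsir(
      sprintf("Code-list file is missing column(s): %s", paste(missing, collapse = ", ")),
      "claimsir_schema_error"
    )
  }
  if (nrow(df) == 0) {
    abort_claimsir("Code-list file has no entries.", "claimsir_codelist_error")
  }
  bad_role <- setdiff(unique(df$role), c("include", "exclude"))
  if (length(bad_role)) {
    abort_claimsir(
      sprintf(
        "Unknown role value(s) %s; allowed: include, exclude.",
        paste(sQuote(bad_role), collapse = ", ")
      ),
      "claimsir_schema_error"
    )
  }
  groups <- split(df, df$list_name)
  lists <- lapply(groups, function(g) {
    rules <- unique(g$match_rule)
    if (length(rules) != 1) {
      abort_claimsir(
        sprintf("Code list '%s' mixes match rules.", g$list_name[1]),
        "claimsir_codelist_error"
      )
    }
    code_list(
      g$list_name[1],
      include = g$entry[g$role == "include"],
      exclude = g$entry[g$role == "exclude"],
      match_rule = rules
    )
  })
  lists
}
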