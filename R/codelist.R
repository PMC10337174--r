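#' Construct a rated clinical codelist
#'
#' A codelist is the unit of case-definition engineering: every candidate
#' code carries an expert rating — `"yes"` (strongly indicative), `"maybe"`
#' (conceivably indicative) or `"no"` (rejected, never matchable). The
#' *narrow* subset is the `"yes"` codes; the *broad* subset is `"yes"` plus
#' `"maybe"`, so narrow is always contained in broad.
#'
#' @param code Character vector of unique code identifiers.
#' @param term Character vector of display terms (recycled if length 1).
#' @param rating Ratings, one of `"yes"`, `"maybe"`, `"no"` (case-folded).
#' @param system Terminology system, `"SNOMED_LIKE"` or `"ICD10"`.
#' @param name Optional codelist name.
#' @return A tibble of class `ipf_codelist` with columns `code`, `term`,
#'   `system`, `rating`.
#' @examples
#' cl <- codelist(c("A", "B", "C"), "t", c("yes", "maybe", "no"))
#' codelist_codes(cl, "narrow")
#' codelist_codes(cl, "broad")
#' @export
codelist <- function(code, term = "", rating = "yes",
                     system = c("SNOMED_LIKE", "ICD10"), name = NULL) {
  system <- match.arg(system)
  rating <- tolower(trimws(rating))
  bad <- setdiff(unique(rating), c("yes", "maybe", "no"))
  if (length(bad)) {
    abort(sprintf("unknown rating token(s): %s", paste(sQuote(bad), collapse = ", ")),
          class = "ipfvalid_parse_error")
  }
  x <- tibble(code = as.character(code),
              term = rep_len(as.character(term), length(code)),
              system = system,
              rating = rep_len(rating, length(code)))
  dup <- duplicated(x$code)
  if (any(dup)) {
    abort(sprintf("duplicate code in codelist: %s", sQuote(x$code[dup][1])),
          class = "ipfvalid_integrity_error")
  }
  structure(x, class = c("ipf_codelist", class(x)), name = name %||% "codelist")
}

#' Read a rated codelist from tab-separated text
#'
#' Expects columns `code`, `term`, `system`, `rating`; ratings are
#' case-folded before validation, so `"Yes"` and `"YES"` are accepted.
#'
#' @param path Path to a TSV file.
#' @param name Codelist name; defaults to the file name.
#' @return An `ipf_codelist` (see [codelist()]).
#' @export
read_codelist <- function(path, name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ipfvalid_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c("code", "term", "system", "rating"), names(raw))
  if (length(missing)) {
    abort(sprintf("%s: codelist requires column(s) %s", path,
                  paste(sQuote(missing), collapse = ", ")),
          class = "ipfvalid_schema_error")
  }
  system <- unique(toupper(raw$system))
  if (length(system) != 1L || !system %in% c("SNOMED_LIKE", "ICD10")) {
    abort(sprintf("%s: codelist 'system' must be a single value, SNOMED_LIKE or ICD10", path),
          class = "ipfvalid_parse_error")
  }
  codelist(raw$code, raw$term, raw$rating, system = system,
           name = name %||% basename(path))
}

#' Extract the matchable codes of a codelist subset
#'
#' @param x An `ipf_codelist`.
#' @param subset `"narrow"` (rated yes), `"broad"` (rated yes or maybe) or
#'   `"all"` (alias for broad; rejected codes are never matchable).
#' @return Character vector of codes.
#' @export
codelist_codes <- function(x, subset = c("broad", "narrow", "all")) {
  subset <- match.arg(subset)
  stopifnot(inherits(x, "ipf_codelist"))
  keep <- switch(subset,
                 narrow = x$rating == "yes",
                 x$rating %in% c("yes", "maybe"))
  x$code[keep]
}

#' @export
print.ipf_codelist <- function(x, ...) {
  cat(sprintf("<codelist '%s'> %d codes (%d narrow / %d broad, %s)\n",
              attr(x, "name"), nrow(x), sum(x$rating == "yes"),
              sum(x$rating %in% c("yes", "maybe")), x$system[1] %||% "?"))
  NextMethod()
}

#' Canonicalise an ICD-10 code
#'
#' Strips surrounding whitespace and internal dots and upper-cases, so that
#' `"J84.1"`, `" j841 "` and `"J841"` all canonicalise to `"J841"`. The
#' operation is idempotent.
#'
#' @param code Character vector of non-empty ICD-10 codes.
#' @return Character vector of canonical codes.
#' @examples
#' normalize_icd10(c("J84.1", " j849 ", "J84.1X"))
#' @export
normalize_icd10 <- function(code) {
  code <- as.character(code)
  if (any(is.na(code) | trimws(code) == "")) {
    abort("empty ICD-10 code", class = "ipfvalid_value_error")
  }
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

#' Match ICD-10 codes against a target set
#'
#' By default matching is prefix-based after canonicalisation: a recorded
#' code qualifies if it equals a target or extends one by trailing
#' characters, so 4th/5th-character subdivisions of a listed 4-character
#' code (e.g. `"J8410"` against target `"J841"`) qualify. Note `"J840"` is
#' not an extension of `"J841"`. Set `exact = TRUE` for equality-only
#' matching.
#'
#' @param code Character vector of recorded codes (any formatting).
#' @param targets Character vector of canonical target codes
#'   (see [normalize_icd10()]).
#' @param exact If `TRUE`, require exact equality after canonicalisation.
#' @return Logical vector, one element per `code`.
#' @examples
#' icd10_matches(c("J84.1", "J840", "J8410"), ipf_icd10_targets())
#' @export
icd10_matches <- function(code, targets, exact = FALSE) {
  norm <- normalize_icd10(code)
  if (length(targets) == 0) return(rep(FALSE, length(norm)))
  if (exact) return(norm %in% targets)
  Reduce(`|`, lapply(targets, function(t) startsWith(norm, t)))
}

#' The qualifying ICD-10 codes for IPF in hospital and death data
#'
#' The three codes used to define IPF hospitalisations and deaths:
#' J84.1 (interstitial pulmonary disease with fibrosis), J84.8 and J84.9,
#' in canonical dotless form.
#'
#' @return `c("J841", "J848", "J849")`.
#' @export
ipf_icd10_targets <- function() c("J841", "J848", "J849")
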