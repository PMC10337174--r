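# Built-in synthetic codelists. These are stand-ins written for this
# package: opaque SNOMED-like identifiers whose terms mirror the vocabulary
# seen in UK primary-care IPF coding (the real rated lists are
# licence-restricted). Ratings follow the usual convention: "yes" codes are
# strongly indicative of IPF (the narrow subset), "maybe" codes denote
# pulmonary fibrosis of unspecified aetiology (broad minus narrow), "no"
# codes are rejected and never matchable.

#' Built-in synthetic primary-care IPF codelist
#'
#' @return An [codelist()] with narrow (`"yes"`) and broad
#'   (`"yes"`/`"maybe"`) subsets.
#' @export
default_ipf_codelist <- function() {
  codelist(
    code = c("IPF-IPF", "IPF-IFA", "IPF-CFA",
             "PF-PULMFIB", "PF-DIFFUSE", "PF-FIBALV", "PF-HONEY",
             "PF-RADIATION"),
    term = c("idiopathic pulmonary fibrosis", "idiopathic fibrosing alveolitis",
             "cryptogenic fibrosing alveolitis",
             "pulmonary fibrosis", "diffuse pulmonary fibrosis",
             "fibrosing alveolitis", "honeycomb lung",
             "radiation fibrosis of lung"),
    rating = c("yes", "yes", "yes",
               "maybe", "maybe", "maybe", "maybe",
               "no"),
    name = "synthetic_ipf"
  )
}

#' Built-in synthetic codelist of other known ILD causes
#'
#' Exclusion codes for the algorithms that require no other known cause of
#' interstitial lung disease: connective tissue disease, sarcoidosis,
#' environmental exposures, drug toxicity, other non-IPF ILD.
#'
#' @return An [codelist()].
#' @export
default_ild_codelist <- function() {
  codelist(
    code = c("ILD-CTD", "ILD-SARC", "ILD-EAA", "ILD-DRUG", "ILD-ASB"),
    term = c("connective tissue disease associated ILD", "pulmonary sarcoidosis",
             "extrinsic allergic alveolitis", "drug-induced interstitial lung disease",
             "asbestosis"),
    rating = "yes",
    name = "synthetic_ild_exclusions"
  )
}

#' Built-in synthetic smoking-status codes
#'
#' @return A tibble with columns `code` and `status`
#'   (`never`/`ex`/`current`).
#' @export
default_smoking_codes <- function() {
  tibble(code = c("SMOK-NEVER", "SMOK-EX", "SMOK-CURRENT"),
         status = c("never", "ex", "current"))
}

#' Built-in synthetic comorbidity codelists
#'
#' @return A named list of character code vectors, one per comorbidity.
#' @export
default_comorbidity_codelists <- function() {
  list(copd = "COM-COPD", asthma = "COM-ASTHMA", lung_cancer = "COM-LUNGCA",
       ischemic_stroke = "COM-STROKE", heart_failure = "COM-HF",
       ischemic_heart_disease = "COM-IHD", myocardial_infarction = "COM-MI",
       gastroesophageal_reflux = "COM-GORD")
}

#' Built-in yearly code-choice weights emulating terminology drift
#'
#' Primary-care code choice for the same clinical concept drifts over
#' calendar time: older terms (fibrosing alveolitis, diffuse pulmonary
#' fibrosis) decline while IPF-specific terms rise. The default weights
#' interpolate linearly between a 2008 and a 2018 profile and are
#' normalised to sum to one within each year.
#'
#' @param years Calendar years covered (default 2008–2018).
#' @return A tibble with columns `year`, `code`, `weight`; weights sum to 1
#'   within each year.
#' @export
default_code_drift <- function(years = 2008:2018) {
  codes <- c("IPF-IPF", "IPF-IFA", "IPF-CFA", "PF-PULMFIB", "PF-DIFFUSE",
             "PF-FIBALV", "PF-HONEY")
  w_start <- c(0.08, 0.10, 0.12, 0.20, 0.25, 0.22, 0.03)
  w_end <- c(0.34, 0.12, 0.04, 0.30, 0.10, 0.07, 0.03)
  frac <- if (length(years) == 1) 0 else
    (years - min(years)) / (max(years) - min(years))
  out <- purrr::map_dfr(seq_along(years), function(i) {
    w <- w_start + frac[i] * (w_end - w_start)
    tibble(year = years[i], code = codes, weight = w / sum(w))
  })
  out
}
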