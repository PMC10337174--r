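#' Diagnosis positions admitted by a position rule
#'
#' Hospital episodes carry up to 20 positioned ICD-10 diagnoses; the
#' position rule decides how far down the list a qualifying code may sit.
#' `primary_or_secondary` admits positions 1–2 (the base case definition),
#' `top3` positions 1–3 (sensitivity analysis), `any_position` 1–20.
#'
#' @param rule One of `"primary_or_secondary"`, `"top3"`, `"any_position"`.
#' @return Integer vector of admissible positions.
#' @export
positions_for_rule <- function(rule = c("primary_or_secondary", "top3",
                                        "any_position")) {
  rule <- match.arg(rule)
  switch(rule,
         primary_or_secondary = 1:2,
         top3 = 1:3,
         any_position = 1:20)
}

#' Define a diagnostic case-finding algorithm
#'
#' An algorithm is a Boolean conjunction over a patient's linked record:
#' a primary-care code-set requirement (broad, narrow or none), optionally
#' a qualifying hospital admission under a position rule, optionally
#' thoracic CT evidence, optionally the absence of codes for other known
#' causes of interstitial lung disease.
#'
#' @param id Identifier (e.g. `"DA1"` or a custom label).
#' @param aurum_codeset `"broad"`, `"narrow"` or `"none"`.
#' @param require_hospitalisation Require a qualifying IPF admission.
#' @param position_rule See [positions_for_rule()].
#' @param require_hrct Require a thoracic CT record at any time.
#' @param exclude_other_ild Exclude patients with a code for another known
#'   ILD cause anywhere in their primary-care record.
#' @param description Free-text description.
#' @return A one-row tibble of class `ipf_algorithm`.
#' @seealso [ipf_algorithms()] for the eight canonical definitions.
#' @export
algorithm <- function(id, aurum_codeset = c("broad", "narrow", "none"),
                      require_hospitalisation = FALSE,
                      position_rule = "primary_or_secondary",
                      require_hrct = FALSE, exclude_other_ild = FALSE,
                      description = "") {
  aurum_codeset <- match.arg(aurum_codeset)
  position_rule <- match.arg(position_rule,
                             c("primary_or_secondary", "top3", "any_position"))
  if (aurum_codeset == "none" && !require_hospitalisation) {
    abort("an algorithm must require a code set or a hospitalisation",
          class = "ipfvalid_config_error")
  }
  structure(tibble(id = id, aurum_codeset = aurum_codeset,
                   require_hospitalisation = require_hospitalisation,
                   position_rule = position_rule,
                   require_hrct = require_hrct,
                   exclude_other_ild = exclude_other_ild,
                   description = description),
            class = c("ipf_algorithm", class(tibble())))
}

#' The eight canonical diagnostic algorithms
#'
#' DA1: any broad primary-care code. DA2: broad code + thoracic CT + no
#' other known ILD cause. DA3: any narrow code. DA4: narrow code + CT + no
#' other ILD cause. DA5: IPF ICD-10 code in primary or secondary position
#' in any hospital episode. DA6: DA5 + thoracic CT. DA7: broad code +
#' qualifying admission. DA8: narrow code + qualifying admission.
#'
#' @param ids Which algorithms to return (default all eight).
#' @return A tibble with one row per algorithm, same columns as
#'   [algorithm()].
#' @export
ipf_algorithms <- function(ids = paste0("DA", 1:8)) {
  defs <- bind_rows(
    algorithm("DA1", "broad", description = "Any broad code in primary care"),
    algorithm("DA2", "broad", require_hrct = TRUE, exclude_other_ild = TRUE,
              description = "Broad code + thoracic CT + no other ILD cause"),
    algorithm("DA3", "narrow", description = "Any narrow code in primary care"),
    algorithm("DA4", "narrow", require_hrct = TRUE, exclude_other_ild = TRUE,
              description = "Narrow code + thoracic CT + no other ILD cause"),
    algorithm("DA5", "none", require_hospitalisation = TRUE,
              description = "IPF admission (primary/secondary position)"),
    algorithm("DA6", "none", require_hospitalisation = TRUE, require_hrct = TRUE,
              description = "IPF admission + thoracic CT"),
    algorithm("DA7", "broad", require_hospitalisation = TRUE,
              description = "Broad code + IPF admission"),
    algorithm("DA8", "narrow", require_hospitalisation = TRUE,
              description = "Narrow code + IPF admission")
  )
  unknown <- setdiff(ids, defs$id)
  if (length(unknown)) {
    abort(sprintf("unknown algorithm id(s): %s", paste(unknown, collapse = ", ")),
          class = "ipfvalid_config_error")
  }
  defs[match(ids, defs$id), ]
}

#' Earliest primary-care event matching a code set, per patient
#'
#' @param events An events table.
#' @param codes Character vector of matchable codes (e.g. from
#'   [codelist_codes()]).
#' @return Tibble with `patient_id` and `first_date` for patients with at
#'   least one match.
#' @export
earliest_code_match <- function(events, codes) {
  events |>
    filter(.data$code %in% codes) |>
    arrange(.data$patient_id, .data$event_date) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select("patient_id", first_date = "event_date")
}

#' First qualifying IPF admission per patient
#'
#' An admission qualifies when its spell contains, in any episode, a
#' diagnosis at a position admitted by `rule` that matches `targets`
#' (prefix semantics, see [icd10_matches()]). When `window` is supplied,
#' only admissions whose admission date falls inside the patient's
#' follow-up window count.
#'
#' @param spells A spells table (one row per positioned diagnosis).
#' @param targets Canonical ICD-10 target codes.
#' @param rule A position rule, see [positions_for_rule()].
#' @param window Optional tibble `patient_id`, `fu_start`, `fu_end`.
#' @param exact Passed to [icd10_matches()].
#' @return Tibble with `patient_id` and `admission_date` (the earliest
#'   qualifying admission); patients with none are absent.
#' @export
qualifying_admissions <- function(spells, targets = ipf_icd10_targets(),
                                  rule = "primary_or_secondary",
                                  window = NULL, exact = FALSE) {
  pos <- positions_for_rule(rule)
  hits <- spells |>
    filter(.data$position %in% pos) |>
    filter(icd10_matches(.data$icd10, targets, exact = exact))
  if (!is.null(window)) {
    hits <- hits |>
      inner_join(window, by = "patient_id") |>
      filter(!is.na(.data$fu_start),
             .data$admission_date >= .data$fu_start,
             .data$admission_date <= .data$fu_end)
  }
  hits |>
    arrange(.data$patient_id, .data$admission_date) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select("patient_id", "admission_date")
}

#' IPF on the death certificate
#'
#' @param deaths A deaths table (long; `cause_rank` 0 = underlying cause).
#' @param targets Canonical ICD-10 target codes.
#' @param mode `"anywhere"` matches the underlying plus all contributory
#'   causes; `"underlying_only"` the underlying cause alone.
#' @return Tibble with `patient_id` and logical `ipf_death` (patients
#'   without a death record are absent).
#' @export
death_has_ipf <- function(deaths, targets = ipf_icd10_targets(),
                          mode = c("anywhere", "underlying_only")) {
  mode <- match.arg(mode)
  d <- if (mode == "underlying_only") filter(deaths, .data$cause_rank == 0L) else deaths
  hit_ids <- unique(d$patient_id[icd10_matches(d$icd10, targets)])
  tibble(patient_id = unique(deaths$patient_id)) |>
    mutate(ipf_death = .data$patient_id %in% hit_ids)
}

#' Thoracic CT evidence, per patient
#'
#' True for patients with at least one imaging event of modality CT and
#' body region thorax, at any time (the imaging source does not flag high
#' resolution, so any thoracic CT qualifies; no date restriction applies).
#'
#' @param imaging An imaging table.
#' @return Tibble with `patient_id` and logical `hrct` for patients with
#'   at least one imaging event.
#' @export
has_hrct_evidence <- function(imaging) {
  hit_ids <- unique(imaging$patient_id[imaging$modality == "CT" &
                                         imaging$body_region == "thorax"])
  tibble(patient_id = unique(imaging$patient_id)) |>
    mutate(hrct = .data$patient_id %in% hit_ids)
}

#' Evidence of another known ILD cause, per patient
#'
#' True when any primary-care event, at any date, matches the exclusion
#' codelist (connective tissue disease, sarcoidosis, environmental
#' exposures, drug toxicity, other non-IPF ILD).
#'
#' @param events An events table.
#' @param exclusion_codelist An `ipf_codelist` of exclusion codes.
#' @return Tibble with `patient_id` and logical `other_ild` for patients
#'   with at least one event.
#' @export
has_other_ild_cause <- function(events, exclusion_codelist) {
  codes <- codelist_codes(exclusion_codelist, "broad")
  hit_ids <- unique(events$patient_id[events$code %in% codes])
  tibble(patient_id = unique(events$patient_id)) |>
    mutate(other_ild = .data$patient_id %in% hit_ids)
}

#' Per-patient case-finding features
#'
#' Reduces a linked cohort to one row per patient carrying everything the
#' diagnostic algorithms and the validation module consume: earliest broad
#' and narrow primary-care code dates, the follow-up window (anchored on
#' the earliest broad code when one exists), first qualifying admissions
#' under each position rule (both window-restricted and unrestricted),
#' thoracic CT and other-ILD flags, death dates and death-certificate IPF
#' status under both gold-standard modes, and study eligibility.
#'
#' @param cohort A [linked_cohort()].
#' @param ipf_codelist Rated primary-care IPF codelist (broad/narrow
#'   subsets are taken from its ratings). Defaults to the built-in
#'   synthetic list.
#' @param exclusion_codelist Rated codelist of other known ILD causes.
#' @param config A [study_config()].
#' @param targets Canonical ICD-10 codes defining IPF in hospital and
#'   death data.
#' @return A tibble, one row per registry patient.
#' @export
patient_features <- function(cohort,
                             ipf_codelist = default_ipf_codelist(),
                             exclusion_codelist = default_ild_codelist(),
                             config = study_config(),
                             targets = ipf_icd10_targets()) {
  stopifnot(inherits(cohort, "linked_cohort"))
  reg <- cohort$registry
  broad <- earliest_code_match(cohort$events, codelist_codes(ipf_codelist, "broad"))
  narrow <- earliest_code_match(cohort$events, codelist_codes(ipf_codelist, "narrow"))
  feats <- reg |>
    select("patient_id", "birth_date", "sex", "death_date") |>
    left_join(rename(broad, broad_date = "first_date"), by = "patient_id") |>
    left_join(rename(narrow, narrow_date = "first_date"), by = "patient_id")
  win <- followup_window(reg, feats$broad_date, config)
  feats <- feats |>
    left_join(win, by = "patient_id") |>
    mutate(eligible = is_study_eligible(reg, feats$broad_date, config))
  for (rule in c("primary_or_secondary", "top3", "any_position")) {
    suffix <- c(primary_or_secondary = "ps", top3 = "top3", any_position = "any")[[rule]]
    inwin <- qualifying_admissions(cohort$spells, targets, rule, window = win)
    ever <- qualifying_admissions(cohort$spells, targets, rule)
    feats <- feats |>
      left_join(stats::setNames(inwin, c("patient_id", paste0("adm_", suffix))),
                by = "patient_id") |>
      left_join(stats::setNames(ever, c("patient_id", paste0("adm_", suffix, "_ever"))),
                by = "patient_id")
  }
  feats <- feats |>
    left_join(has_hrct_evidence(cohort$imaging), by = "patient_id") |>
    left_join(has_other_ild_cause(cohort$events, exclusion_codelist),
              by = "patient_id") |>
    left_join(stats::setNames(death_has_ipf(cohort$deaths, targets, "anywhere"),
                              c("patient_id", "ipf_death_any")), by = "patient_id") |>
    left_join(stats::setNames(death_has_ipf(cohort$deaths, targets, "underlying_only"),
                              c("patient_id", "ipf_death_underlying")),
              by = "patient_id") |>
    mutate(across(c("hrct", "other_ild", "ipf_death_any", "ipf_death_underlying"),
                  ~ !is.na(.x) & .x),
           deceased = !is.na(.data$death_date))
  feats
}

#' Apply a diagnostic algorithm to per-patient features
#'
#' Evaluates the algorithm's conjunction on each patient: code-set match,
#' qualifying admission inside the follow-up window under the algorithm's
#' position rule, thoracic CT, and (negated) other-ILD exclusion. Pure:
#' identical inputs give identical outputs and patient order is irrelevant.
#'
#' @param features Output of [patient_features()].
#' @param da A one-row algorithm definition ([algorithm()] or one row of
#'   [ipf_algorithms()]).
#' @return Logical vector aligned with `features` rows.
#' @export
apply_algorithm <- function(features, da) {
  stopifnot(is.data.frame(da), nrow(da) == 1)
  ok <- rep(TRUE, nrow(features))
  ok <- ok & switch(da$aurum_codeset,
                    broad = !is.na(features$broad_date),
                    narrow = !is.na(features$narrow_date),
                    none = TRUE,
                    abort(sprintf("unknown code set '%s'", da$aurum_codeset),
                          class = "ipfvalid_config_error"))
  if (isTRUE(da$require_hospitalisation)) {
    col <- paste0("adm_", c(primary_or_secondary = "ps", top3 = "top3",
                            any_position = "any")[[da$position_rule]])
    ok <- ok & !is.na(features[[col]])
  }
  if (isTRUE(da$require_hrct)) ok <- ok & features$hrct
  if (isTRUE(da$exclude_other_ild)) ok <- ok & !features$other_ild
  ok
}
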