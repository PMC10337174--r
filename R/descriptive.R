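#' Yearly usage of primary-care IPF codes
#'
#' Counts matching primary-care events by calendar year and code (each
#' event matches exactly one code identifier, so yearly totals equal the
#' number of matching events) and derives each code's share of its year.
#' Also reports, as attributes, the overall top-`k` codes across the whole
#' range and their aggregate share.
#'
#' @param events An events table.
#' @param ipf_codelist Rated codelist; the broad subset is counted.
#' @param years Calendar years to cover (non-empty).
#' @param top_k How many leading codes the aggregate share covers.
#' @return A tibble of class `ipf_trend` with columns `year`, `code`,
#'   `term`, `n`, `share` (share within year), and attributes `top_codes`
#'   and `top_share`.
#' @export
code_usage_by_year <- function(events, ipf_codelist = default_ipf_codelist(),
                               years = 2008:2018, top_k = 4) {
  if (length(years) == 0) {
    abort("year range is empty", class = "ipfvalid_value_error")
  }
  codes <- codelist_codes(ipf_codelist, "broad")
  terms <- tibble(code = ipf_codelist$code, term = ipf_codelist$term)
  tab <- events |>
    filter(.data$code %in% codes) |>
    mutate(year = as.integer(format(.data$event_date, "%Y"))) |>
    filter(.data$year %in% years) |>
    count(.data$year, .data$code, name = "n") |>
    left_join(terms, by = "code") |>
    group_by(.data$year) |>
    mutate(share = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("year", "code", "term", "n", "share") |>
    arrange(.data$year, dplyr::desc(.data$n), .data$code)
  totals <- tab |> count(.data$code, wt = .data$n, name = "n", sort = TRUE)
  top <- utils::head(totals$code, top_k)
  top_share <- if (sum(totals$n) > 0) {
    sum(totals$n[totals$code %in% top]) / sum(totals$n)
  } else NA_real_
  structure(tab, class = c("ipf_trend", class(tab)),
            top_codes = top, top_share = top_share)
}

completed_age <- function(birth, at) {
  y <- as.integer(format(at, "%Y")) - as.integer(format(birth, "%Y"))
  before_birthday <- format(at, "%m-%d") < format(birth, "%m-%d")
  y - as.integer(before_birthday)
}

#' Demographic and clinical profile of a patient subset
#'
#' Summarises a cohort at its index date: median (IQR) age in completed
#' years, share aged 65 or over, share male, smoking history (the closest
#' record at or before index; the later record wins ties; patients without
#' any smoking record form an unknown bucket excluded from both numerator
#' and denominator), per-comorbidity share (any matching code strictly
#' before index) and median (IQR) survival in years from index to death
#' among the deceased.
#'
#' @param cohort A [linked_cohort()].
#' @param ids Patient ids to profile; default all patients with an index
#'   date under `index_rule`.
#' @param index_rule `"earliest_aurum_code"` (the earliest broad
#'   primary-care code) or `"earliest_admission"` (the first qualifying
#'   admission).
#' @param comorbidity_codelists Named list of code vectors.
#' @param smoking_codes Tibble with columns `code`, `status`.
#' @param config A [study_config()].
#' @param features Optional precomputed [patient_features()].
#' @return A one-row tibble: `n`, age and survival summaries, and one
#'   `pct_*` column per characteristic (percent scale).
#' @export
cohort_profile <- function(cohort, ids = NULL,
                           index_rule = c("earliest_aurum_code",
                                          "earliest_admission"),
                           comorbidity_codelists = default_comorbidity_codelists(),
                           smoking_codes = default_smoking_codes(),
                           config = study_config(), features = NULL) {
  index_rule <- match.arg(index_rule)
  if (is.null(features)) features <- patient_features(cohort, config = config)
  idx_col <- if (index_rule == "earliest_aurum_code") "broad_date" else "adm_ps"
  sub <- features |>
    mutate(index_date = .data[[idx_col]]) |>
    filter(!is.na(.data$index_date))
  if (!is.null(ids)) sub <- sub |> filter(.data$patient_id %in% ids)
  if (nrow(sub) == 0) {
    abort("empty cohort: nobody has an index date under this rule",
          class = "ipfvalid_value_error")
  }
  age <- completed_age(sub$birth_date, sub$index_date)

  smk <- cohort$events |>
    inner_join(smoking_codes, by = "code") |>
    inner_join(sub |> select("patient_id", "index_date"), by = "patient_id") |>
    filter(.data$event_date <= .data$index_date) |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$patient_id) |>
    arrange(.data$event_date, .data$.row, .by_group = TRUE) |>
    summarise(status = dplyr::last(.data$status), .groups = "drop")
  n_known <- nrow(smk)
  pct_smoker <- if (n_known > 0) 100 * mean(smk$status %in% c("ex", "current")) else NA_real_

  com <- purrr::imap(comorbidity_codelists, function(codes, nm) {
    hit <- cohort$events |>
      filter(.data$code %in% codes) |>
      inner_join(sub |> select("patient_id", "index_date"), by = "patient_id") |>
      filter(.data$event_date < .data$index_date) |>
      distinct(.data$patient_id)
    100 * nrow(hit) / nrow(sub)
  })
  names(com) <- paste0("pct_", names(com))

  dead <- sub |> filter(.data$deceased)
  surv <- as.numeric(dead$death_date - dead$index_date) / 365.25
  out <- tibble(
    n = nrow(sub),
    age_median = stats::median(age),
    age_iqr = stats::IQR(age),
    pct_ge65 = 100 * mean(age >= 65),
    pct_male = 100 * mean(sub$sex == "male"),
    pct_smoker = pct_smoker,
    n_smoking_known = n_known,
    survival_median_years = if (length(surv)) stats::median(surv) else NA_real_,
    survival_iqr_years = if (length(surv)) stats::IQR(surv) else NA_real_)
  bind_cols(out, as_tibble(com))
}

#' Underlying causes of death among source-discordant patients
#'
#' Among study-eligible decedents flagged by one source (primary care or
#' hospital) but with no IPF code anywhere on the death certificate,
#' tallies the underlying causes of death, ranked by descending count with
#' ties broken lexicographically.
#'
#' @param cohort A [linked_cohort()].
#' @param source `"aurum"` or `"hes"` — which cohort to take discordant
#'   members from.
#' @param config A [study_config()].
#' @param features Optional precomputed [patient_features()].
#' @return A tibble with columns `icd10` (canonical underlying cause) and
#'   `n`, ranked.
#' @export
discordant_death_causes <- function(cohort, source = c("aurum", "hes"),
                                    config = study_config(), features = NULL) {
  source <- match.arg(source)
  if (is.null(features)) features <- patient_features(cohort, config = config)
  sets <- membership_sets(features, config, "anywhere")
  ids <- setdiff(sets[[source]], sets$ons)
  cohort$deaths |>
    filter(.data$cause_rank == 0L, .data$patient_id %in% ids) |>
    mutate(icd10 = normalize_icd10(.data$icd10)) |>
    count(.data$icd10, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$icd10)
}
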