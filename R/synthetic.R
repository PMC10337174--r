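#' Configuration for the stochastic linked-cohort generator
#'
#' The generator emulates the structure of a linked decedent cohort of
#' possible-IPF patients: a latent true-IPF label per patient, imperfect
#' primary-care coding (with calendar drift in code choice), imperfect
#' hospital recording with positioned diagnoses, thoracic imaging, and a
#' death certificate on which true cases appear with a given probability,
#' as underlying or contributory cause. Every generated patient dies inside
#' the date range: all validation quantities condition on death, so the
#' generator produces the decedent population directly.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; the same configuration generates identical
#'   output.
#' @param p_true_ipf Probability a patient truly has IPF.
#' @param p_gp_broad_given_ipf,p_gp_broad_given_not Probability of at least
#'   one broad primary-care code, for true cases and non-cases.
#' @param p_narrow_given_broad Probability a broad-coded patient also
#'   carries a narrow (strongly indicative) code.
#' @param p_hosp_given_ipf,p_hosp_given_not Probability of a qualifying
#'   hospital admission.
#' @param p_death_cert_given_ipf Probability a true case has IPF anywhere
#'   on the death certificate; non-cases never do (this convention keeps
#'   the expected-PPV oracle closed form).
#' @param p_underlying_given_cert Probability a certificate IPF code is the
#'   underlying (rather than a contributory) cause.
#' @param p_hrct Probability of a thoracic CT record.
#' @param p_other_ild Probability of a code for another known ILD cause.
#' @param p_position3_only Probability that a hospitalised patient's IPF
#'   code sits only in diagnostic position 3 (so it qualifies under the
#'   top-3 rule but not the primary-or-secondary rule).
#' @param code_drift Per-year code-choice weights, see
#'   [default_code_drift()].
#' @param birth_range,registration_range,death_range Date ranges
#'   (length-2, coercible to `Date`) for birth, registration start and
#'   death.
#' @return A validated list of class `ipf_generator_config`.
#' @export
generator_config <- function(n_patients = 20000L, seed = 1L,
                             p_true_ipf = 0.65,
                             p_gp_broad_given_ipf = 0.60,
                             p_gp_broad_given_not = 0.35,
                             p_narrow_given_broad = 0.19,
                             p_hosp_given_ipf = 0.65,
                             p_hosp_given_not = 0.30,
                             p_death_cert_given_ipf = 0.85,
                             p_underlying_given_cert = 0.62,
                             p_hrct = 0.45,
                             p_other_ild = 0.10,
                             p_position3_only = 0.15,
                             code_drift = default_code_drift(),
                             birth_range = c("1930-01-01", "1955-12-31"),
                             registration_range = c("1995-01-01", "2007-12-31"),
                             death_range = c("2009-01-01", "2018-12-01")) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              p_true_ipf = p_true_ipf,
              p_gp_broad_given_ipf = p_gp_broad_given_ipf,
              p_gp_broad_given_not = p_gp_broad_given_not,
              p_narrow_given_broad = p_narrow_given_broad,
              p_hosp_given_ipf = p_hosp_given_ipf,
              p_hosp_given_not = p_hosp_given_not,
              p_death_cert_given_ipf = p_death_cert_given_ipf,
              p_underlying_given_cert = p_underlying_given_cert,
              p_hrct = p_hrct, p_other_ild = p_other_ild,
              p_position3_only = p_position3_only,
              code_drift = code_drift,
              birth_range = as.Date(birth_range),
              registration_range = as.Date(registration_range),
              death_range = as.Date(death_range))
  probs <- cfg[startsWith(names(cfg), "p_")]
  bad <- names(probs)[vapply(probs, function(p) !is.numeric(p) || is.na(p) ||
                               p < 0 || p > 1, logical(1))]
  if (length(bad)) {
    abort(sprintf("generator probabilities must lie in [0, 1]: %s",
                  paste(bad, collapse = ", ")),
          class = "ipfvalid_config_error")
  }
  if (cfg$n_patients < 1) {
    abort("n_patients must be >= 1", class = "ipfvalid_config_error")
  }
  sums <- code_drift |> group_by(.data$year) |> summarise(s = sum(.data$weight))
  if (any(abs(sums$s - 1) > 1e-8)) {
    abort("code_drift weights must sum to 1 within each year",
          class = "ipfvalid_config_error")
  }
  structure(cfg, class = "ipf_generator_config")
}

runif_dates <- function(n, range) {
  as.Date(round(stats::runif(n, as.numeric(range[1]), as.numeric(range[2]))),
          origin = "1970-01-01")
}

draw_drift_code <- function(years, drift, codes) {
  # sample a code per event from the drift weights of its calendar year,
  # restricted (and renormalised) to `codes`
  drift <- drift |> filter(.data$code %in% codes)
  yrs <- sort(unique(drift$year))
  years_clamped <- pmin(pmax(years, min(yrs)), max(yrs))
  out <- character(length(years))
  for (y in unique(years_clamped)) {
    w <- drift |> filter(.data$year == y)
    idx <- years_clamped == y
    out[idx] <- sample(w$code, sum(idx), replace = TRUE, prob = w$weight)
  }
  out
}

#' Generate a stochastic linked cohort with known ground truth
#'
#' Draws a decedent cohort from [generator_config()]: registry rows,
#' primary-care events (IPF codes drawn from the per-year drift weights,
#' plus smoking and comorbidity codes), hospital spells with positioned
#' diagnoses, death-certificate causes and imaging events, together with a
#' `truth` tibble of the latent labels. Output is reproducible for a fixed
#' config and passes all structural table invariants.
#'
#' @param config A [generator_config()].
#' @return A [linked_cohort()]; its `truth` element has one row per patient
#'   with the latent labels (`true_ipf`, `broad_coded`, `narrow_coded`,
#'   `hospitalised`, `position3_only`, `cert_ipf`, `cert_underlying`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "ipf_generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  id <- sprintf("S%07d", seq_len(n))

  birth <- runif_dates(n, config$birth_range)
  reg <- runif_dates(n, config$registration_range)
  death <- runif_dates(n, config$death_range)
  diag <- death - sample(60:1825, n, replace = TRUE)
  diag <- pmax(diag, config$death_range[1] - 365, reg + 30)
  diag <- pmin(diag, death - 1)

  true_ipf <- stats::runif(n) < config$p_true_ipf
  p_broad <- ifelse(true_ipf, config$p_gp_broad_given_ipf, config$p_gp_broad_given_not)
  broad <- stats::runif(n) < p_broad
  narrow <- broad & (stats::runif(n) < config$p_narrow_given_broad)
  p_hosp <- ifelse(true_ipf, config$p_hosp_given_ipf, config$p_hosp_given_not)
  hosp <- stats::runif(n) < p_hosp
  pos3 <- hosp & (stats::runif(n) < config$p_position3_only)
  hrct <- stats::runif(n) < config$p_hrct
  ild <- stats::runif(n) < config$p_other_ild
  cert <- true_ipf & (stats::runif(n) < config$p_death_cert_given_ipf)
  underlying <- cert & (stats::runif(n) < config$p_underlying_given_cert)

  registry <- tibble(patient_id = id, birth_date = birth,
                     sex = sample(c("male", "female"), n, replace = TRUE,
                                  prob = c(0.62, 0.38)),
                     registration_start = reg,
                     last_collection_date = as.Date("2020-06-30"),
                     transfer_out_date = as.Date(NA),
                     death_date = death)

  ipf_cl <- default_ipf_codelist()
  narrow_codes <- codelist_codes(ipf_cl, "narrow")
  maybe_codes <- setdiff(codelist_codes(ipf_cl, "broad"), narrow_codes)
  yr <- as.integer(format(diag, "%Y"))
  ev_ipf <- tibble(patient_id = id[broad], event_date = diag[broad],
                   code = NA_character_, term = "ipf code")
  bn <- narrow[broad]
  ev_ipf$code[bn] <- draw_drift_code(yr[broad][bn], config$code_drift, narrow_codes)
  ev_ipf$code[!bn] <- draw_drift_code(yr[broad][!bn], config$code_drift, maybe_codes)

  smok <- default_smoking_codes()
  ev_smok <- tibble(patient_id = id, event_date = reg + 200,
                    code = sample(smok$code, n, replace = TRUE,
                                  prob = c(0.30, 0.35, 0.35)),
                    term = "smoking status")
  com <- default_comorbidity_codelists()
  ev_com <- purrr::map_dfr(names(com), function(nm) {
    has <- stats::runif(n) < 0.12
    tibble(patient_id = id[has],
           event_date = diag[has] - sample(30:1500, sum(has), replace = TRUE),
           code = com[[nm]][1], term = nm)
  })
  ev_ild <- tibble(patient_id = id[ild],
                   event_date = diag[ild] - sample(-300:300, sum(ild), replace = TRUE),
                   code = sample(codelist_codes(default_ild_codelist()),
                                 sum(ild), replace = TRUE),
                   term = "other ILD cause")
  events <- bind_rows(ev_ipf, ev_smok, ev_com, ev_ild) |>
    arrange(.data$patient_id, .data$event_date, .data$code)

  n_h <- sum(hosp)
  adm <- pmin(diag[hosp] + sample(0:400, n_h, replace = TRUE), death[hosp])
  disc <- pmin(adm + sample(1:20, n_h, replace = TRUE), death[hosp])
  disc <- pmax(disc, adm)
  j84 <- sample(c("J841", "J848", "J849"), n_h, replace = TRUE,
                prob = c(0.70, 0.10, 0.20))
  p3 <- pos3[hosp]
  j84pos <- ifelse(p3, 3L, sample(1:2, n_h, replace = TRUE))
  hid <- id[hosp]
  spells <- bind_rows(
    tibble(patient_id = hid, admission_date = adm, discharge_date = disc,
           episode_index = 1L, position = 1L,
           icd10 = ifelse(j84pos == 1L, j84, "I509")),
    tibble(patient_id = hid, admission_date = adm, discharge_date = disc,
           episode_index = 1L, position = 2L,
           icd10 = ifelse(j84pos == 2L, j84, "J189")),
    tibble(patient_id = hid[p3], admission_date = adm[p3],
           discharge_date = disc[p3], episode_index = 1L, position = 3L,
           icd10 = j84[p3])
  ) |> arrange(.data$patient_id, .data$admission_date, .data$position)

  im_ct <- tibble(patient_id = id[hrct], event_date = diag[hrct] + 30,
                  modality = "CT", body_region = "thorax")
  xr <- stats::runif(n) < 0.30
  im_xr <- tibble(patient_id = id[xr], event_date = diag[xr] - 10,
                  modality = "XRAY", body_region = "thorax")
  imaging <- bind_rows(im_ct, im_xr) |> arrange(.data$patient_id)

  other_causes <- c("J189", "J180", "C349", "J449", "R688", "J969", "I219",
                    "I500", "A419")
  other_probs <- c(0.22, 0.12, 0.14, 0.12, 0.08, 0.08, 0.10, 0.07, 0.07)
  cert_code <- sample(c("J841", "J849", "J848"), n, replace = TRUE,
                      prob = c(0.70, 0.22, 0.08))
  nonipf <- sample(other_causes, n, replace = TRUE, prob = other_probs)
  deaths <- bind_rows(
    tibble(patient_id = id, death_date = death, cause_rank = 0L,
           icd10 = ifelse(cert & underlying, cert_code, nonipf)),
    tibble(patient_id = id[cert & !underlying], death_date = death[cert & !underlying],
           cause_rank = 1L, icd10 = cert_code[cert & !underlying]),
    tibble(patient_id = id[cert & underlying],
           death_date = death[cert & underlying], cause_rank = 1L,
           icd10 = "I509")
  ) |> arrange(.data$patient_id, .data$cause_rank)

  truth <- tibble(patient_id = id, true_ipf = true_ipf, broad_coded = broad,
                  narrow_coded = narrow, hospitalised = hosp,
                  position3_only = pos3, cert_ipf = cert,
                  cert_underlying = underlying, diagnosis_date = diag)
  linked_cohort(registry, events, spells, deaths, imaging, truth = truth)
}

#' Closed-form expected PPV of the broad-code algorithm under the generator
#'
#' Under the generative model, non-IPF patients never receive certificate
#' IPF codes, so among deceased broad-coded patients the probability of a
#' certificate IPF record is
#' \deqn{\frac{p_{true}\,p_{code|IPF}\,p_{cert}}{p_{true}\,p_{code|IPF} +
#'   (1-p_{true})\,p_{code|\neg IPF}}.}
#' Used as the analytic oracle for parameter-recovery tests of the
#' generator plus validation pipeline.
#'
#' @param config A [generator_config()].
#' @return A probability.
#' @export
expected_ppv <- function(config) {
  stopifnot(inherits(config, "ipf_generator_config"))
  denom <- config$p_true_ipf * config$p_gp_broad_given_ipf +
    (1 - config$p_true_ipf) * config$p_gp_broad_given_not
  if (denom == 0) {
    abort("expected PPV undefined: nobody is ever broad-coded",
          class = "ipfvalid_value_error")
  }
  config$p_true_ipf * config$p_gp_broad_given_ipf *
    config$p_death_cert_given_ipf / denom
}
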