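# Shared builders for small in-code fixtures.

mini_cohort_dir <- function() {
  system.file("extdata", "mini_cohort", package = "ipfvalid")
}

make_registry <- function(patient_id = "p1",
                          birth_date = "1940-01-01",
                          sex = "male",
                          registration_start = "2000-01-01",
                          last_collection_date = "2019-06-30",
                          transfer_out_date = NA,
                          death_date = "2015-06-30") {
  tibble::tibble(
    patient_id = patient_id,
    birth_date = as.Date(birth_date),
    sex = sex,
    registration_start = as.Date(registration_start),
    last_collection_date = as.Date(last_collection_date),
    transfer_out_date = as.Date(transfer_out_date),
    death_date = as.Date(death_date))
}

make_events <- function(patient_id, event_date, code, term = "t") {
  tibble::tibble(patient_id = patient_id, event_date = as.Date(event_date),
                 code = code, term = term)
}

make_spell <- function(patient_id, admission_date, icd10_by_position,
                       episode_index = 1L, los = 7) {
  adm <- as.Date(admission_date)
  tibble::tibble(patient_id = patient_id, admission_date = adm,
                 discharge_date = adm + los, episode_index = episode_index,
                 position = seq_along(icd10_by_position),
                 icd10 = icd10_by_position)
}

make_deaths <- function(patient_id, death_date, underlying,
                        contributory = character()) {
  tibble::tibble(
    patient_id = patient_id, death_date = as.Date(death_date),
    cause_rank = c(0L, seq_along(contributory)),
    icd10 = c(underlying, contributory))
}

make_imaging <- function(patient_id, event_date, modality = "CT",
                         body_region = "thorax") {
  tibble::tibble(patient_id = patient_id, event_date = as.Date(event_date),
                 modality = modality, body_region = body_region)
}

# one patient with a full linked record, the building block for
# case-finding unit tests
one_patient_cohort <- function(id = "p1", events = NULL, spells = NULL,
                               deaths = NULL, imaging = NULL, ...) {
  linked_cohort(make_registry(id, ...), events, spells, deaths, imaging)
}

random_registry <- function(n) {
  birth <- as.Date("1920-01-01") + sample(0:30000, n, replace = TRUE)
  reg <- as.Date("1990-01-01") + sample(0:10000, n, replace = TRUE)
  death <- as.Date("2000-01-01") + sample(0:8000, n, replace = TRUE)
  has_death <- runif(n) < 0.7
  has_lcd <- runif(n) < 0.8
  has_tout <- runif(n) < 0.3
  lcd <- as.Date("2005-01-01") + sample(0:6000, n, replace = TRUE)
  tout <- reg + sample(0:6000, n, replace = TRUE)
  tibble::tibble(
    patient_id = sprintf("r%05d", seq_len(n)),
    birth_date = birth,
    sex = sample(c("male", "female", "unknown"), n, replace = TRUE),
    registration_start = pmax(reg, birth + 1),
    last_collection_date = dplyr::if_else(has_lcd, pmax(lcd, birth + 1),
                                          as.Date(NA)),
    transfer_out_date = dplyr::if_else(has_tout, pmax(tout, birth + 1),
                                       as.Date(NA)),
    death_date = dplyr::if_else(has_death, pmax(death, birth + 1), as.Date(NA)))
}
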