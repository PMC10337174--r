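#' Study configuration
#'
#' Holds the study window and eligibility parameters: the default window is
#' 1 January 2008 to 31 December 2018, adulthood is 18 years, and death
#' records may confirm a primary-care code recorded up to `death_grace_days`
#' (60) after death — the grace period applies only where concordance
#' membership is built, never to follow-up windows.
#'
#' @param study_start,study_end Calendar dates bounding the study period.
#' @param adult_age_years Minimum age in completed years.
#' @param death_grace_days Non-negative number of days after death within
#'   which a primary-care code still counts for concordance membership.
#' @return A list of class `ipf_study_config`.
#' @export
study_config <- function(study_start = as.Date("2008-01-01"),
                         study_end = as.Date("2018-12-31"),
                         adult_age_years = 18L,
                         death_grace_days = 60L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(study_start < study_end, adult_age_years >= 0, death_grace_days >= 0)
  structure(list(study_start = study_start, study_end = study_end,
                 adult_age_years = as.integer(adult_age_years),
                 death_grace_days = as.integer(death_grace_days)),
            class = "ipf_study_config")
}

#' @export
print.ipf_study_config <- function(x, ...) {
  cat(sprintf("<study config> %s to %s; adult age %d; death grace %d days\n",
              x$study_start, x$study_end, x$adult_age_years, x$death_grace_days))
  invisible(x)
}

#' Date at which a person reaches a given age
#'
#' Same month and day `years` later; a 29 February birthday rolls to
#' 1 March in non-leap years.
#'
#' @param birth_date Vector of birth dates.
#' @param years Non-negative integer age in completed years.
#' @return Vector of dates.
#' @examples
#' birthday_at_age(as.Date(c("1950-01-01", "1952-02-29")), 18)
#' @export
birthday_at_age <- function(birth_date, years) {
  stopifnot(years >= 0)
  birth_date <- as.Date(birth_date)
  y <- as.integer(format(birth_date, "%Y")) + as.integer(years)
  md <- format(birth_date, "-%m-%d")
  out <- as.Date(paste0(y, md), format = "%Y-%m-%d")
  feb29 <- md == "-02-29" & is.na(out)
  if (any(feb29)) {
    out[feb29] <- as.Date(paste0(y[feb29], "-03-01"), format = "%Y-%m-%d")
  }
  out
}

#' Usable follow-up window for each patient
#'
#' Follow-up starts on the latest of the study start, the IPF diagnosis
#' date (when present), the start of current registration and the 18th
#' birthday; it ends on the earliest of the study end, death, last data
#' collection and transfer out (absent dates are skipped, never defaulted).
#' A window exists only when it contains at least one day, counting the
#' start day inclusive (`start <= end`); otherwise both bounds are `NA`.
#'
#' @param registry A registry tibble (see [read_ehr_table()]).
#' @param diagnosis_date Vector of diagnosis dates aligned with `registry`
#'   rows, `NA` where the patient has no qualifying primary-care code.
#' @param config A [study_config()].
#' @return A tibble with `patient_id`, `fu_start`, `fu_end` (`NA`/`NA` when
#'   no usable follow-up exists).
#' @export
followup_window <- function(registry, diagnosis_date = NULL,
                            config = study_config()) {
  n <- nrow(registry)
  if (is.null(diagnosis_date)) diagnosis_date <- rep(as.Date(NA), n)
  diagnosis_date <- as.Date(diagnosis_date)
  stopifnot(length(diagnosis_date) == n)
  adult <- birthday_at_age(registry$birth_date, config$adult_age_years)
  start <- pmax(config$study_start, registry$registration_start, adult)
  start <- pmax(start, diagnosis_date, na.rm = FALSE)
  start[is.na(diagnosis_date)] <- pmax(config$study_start,
                                       registry$registration_start,
                                       adult)[is.na(diagnosis_date)]
  end_mat <- cbind(as.numeric(config$study_end),
                   as.numeric(registry$death_date),
                   as.numeric(registry$last_collection_date),
                   as.numeric(registry$transfer_out_date))
  end <- as.Date(apply(end_mat, 1, min, na.rm = TRUE), origin = "1970-01-01")
  none <- start > end
  start[none] <- as.Date(NA)
  end[none] <- as.Date(NA)
  tibble(patient_id = registry$patient_id, fu_start = start, fu_end = end)
}

#' Study eligibility
#'
#' A patient is eligible when they are at least `adult_age_years` old at
#' the study start and at (strictly by) their IPF diagnosis when one
#' exists, and they have a usable follow-up window.
#'
#' @inheritParams followup_window
#' @return Logical vector aligned with `registry` rows.
#' @export
is_study_eligible <- function(registry, diagnosis_date = NULL,
                              config = study_config()) {
  n <- nrow(registry)
  if (is.null(diagnosis_date)) diagnosis_date <- rep(as.Date(NA), n)
  diagnosis_date <- as.Date(diagnosis_date)
  adult <- birthday_at_age(registry$birth_date, config$adult_age_years)
  age_ok <- adult <= config$study_start &
    (is.na(diagnosis_date) | adult <= diagnosis_date)
  win <- followup_window(registry, diagnosis_date, config)
  age_ok & !is.na(win$fu_start)
}
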