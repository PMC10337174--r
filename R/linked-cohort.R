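#' Bundle the five linked tables into one cohort object
#'
#' A `linked_cohort` is the package's working unit: one registry row per
#' patient plus the patient's primary-care events, hospital spells (long,
#' one row per positioned diagnosis), death-certificate causes and imaging
#' events. Cross-table consistency is checked on construction: every event
#' belongs to a registered patient, and certificate death dates agree with
#' the registry.
#'
#' @param registry,events,spells,deaths,imaging Tables conforming to the
#'   five schemas of [read_ehr_table()]; missing ones default to empty.
#' @param truth Optional per-patient ground-truth tibble (used by the
#'   synthetic generator), carried along unvalidated.
#' @return A list of class `linked_cohort`.
#' @export
linked_cohort <- function(registry, events = NULL, spells = NULL,
                          deaths = NULL, imaging = NULL, truth = NULL) {
  empty <- list(
    events = tibble(patient_id = character(), event_date = as.Date(character()),
                    code = character(), term = character()),
    spells = tibble(patient_id = character(), admission_date = as.Date(character()),
                    discharge_date = as.Date(character()),
                    episode_index = integer(), position = integer(),
                    icd10 = character()),
    deaths = tibble(patient_id = character(), death_date = as.Date(character()),
                    cause_rank = integer(), icd10 = character()),
    imaging = tibble(patient_id = character(), event_date = as.Date(character()),
                     modality = character(), body_region = character())
  )
  registry <- validate_ehr_table(registry, "registry", "registry")
  events <- validate_ehr_table(events %||% empty$events, "events", "events")
  spells <- validate_ehr_table(spells %||% empty$spells, "spells", "spells")
  deaths <- validate_ehr_table(deaths %||% empty$deaths, "deaths", "deaths")
  imaging <- validate_ehr_table(imaging %||% empty$imaging, "imaging", "imaging")
  known <- registry$patient_id
  for (nm in c("events", "spells", "deaths", "imaging")) {
    tab <- get(nm)
    stray <- setdiff(unique(tab$patient_id), known)
    if (length(stray)) {
      abort(sprintf("%s: patient_id %s not present in registry", nm,
                    sQuote(stray[1])),
            class = "ipfvalid_integrity_error")
    }
  }
  if (nrow(deaths)) {
    cmp <- deaths |>
      distinct(.data$patient_id, .data$death_date) |>
      inner_join(registry |> select("patient_id", reg_death = "death_date"),
                 by = "patient_id") |>
      filter(!is.na(.data$reg_death), .data$death_date != .data$reg_death)
    if (nrow(cmp)) {
      abort(sprintf("death record date for patient %s disagrees with registry",
                    sQuote(cmp$patient_id[1])),
            class = "ipfvalid_integrity_error")
    }
  }
  structure(list(registry = registry, events = events, spells = spells,
                 deaths = deaths, imaging = imaging, truth = truth),
            class = "linked_cohort")
}

#' @export
print.linked_cohort <- function(x, ...) {
  cat(sprintf(paste0("<linked cohort> %d patients; %d primary-care events; ",
                     "%d positioned hospital diagnoses; %d death-cause rows; ",
                     "%d imaging events\n"),
              nrow(x$registry), nrow(x$events), nrow(x$spells),
              nrow(x$deaths), nrow(x$imaging)))
  invisible(x)
}

#' Write / read a linked cohort as a directory of delimited tables
#'
#' @param cohort A [linked_cohort()].
#' @param dir Directory path (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `linked_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "linked_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in ehr_schemas()) {
    write_ehr_table(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  if (!is.null(cohort$truth)) {
    readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tabs <- lapply(ehr_schemas(), function(nm) {
    read_ehr_table(file.path(dir, paste0(nm, ".csv")), nm)
  })
  names(tabs) <- ehr_schemas()
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
  }
  linked_cohort(tabs$registry, tabs$events, tabs$spells, tabs$deaths,
                tabs$imaging, truth = truth)
}
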