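#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Column layouts of the five flat tables. Dates are ISO-8601 (YYYY-MM-DD),
# optional dates may be empty. `spells` is long: one row per positioned
# diagnosis; `deaths` is long: cause_rank 0 is the underlying cause,
# 1..n are contributory causes.
.ehr_schemas <- list(
  registry = list(
    cols = c("patient_id", "birth_date", "sex", "registration_start",
             "last_collection_date", "transfer_out_date", "death_date"),
    dates = c("birth_date", "registration_start", "last_collection_date",
              "transfer_out_date", "death_date"),
    optional_dates = c("last_collection_date", "transfer_out_date", "death_date")
  ),
  events = list(
    cols = c("patient_id", "event_date", "code", "term"),
    dates = "event_date", optional_dates = character()
  ),
  spells = list(
    cols = c("patient_id", "admission_date", "discharge_date",
             "episode_index", "position", "icd10"),
    dates = c("admission_date", "discharge_date"), optional_dates = character()
  ),
  deaths = list(
    cols = c("patient_id", "death_date", "cause_rank", "icd10"),
    dates = "death_date", optional_dates = character()
  ),
  imaging = list(
    cols = c("patient_id", "event_date", "modality", "body_region"),
    dates = "event_date", optional_dates = character()
  )
)

#' Names of the five linked-EHR table schemas
#'
#' @return Character vector: `"registry"`, `"events"`, `"spells"`,
#'   `"deaths"`, `"imaging"`.
#' @export
ehr_schemas <- function() names(.ehr_schemas)

parse_iso_dates <- function(x, col, optional = FALSE, context = "input") {
  x <- trimws(as.character(x))
  blank <- is.na(x) | x == ""
  out <- rep(as.Date(NA), length(x))
  if (any(!blank)) {
    parsed <- as.Date(vapply(x[!blank], function(v) {
      d <- tryCatch(as.Date(v, format = "%Y-%m-%d"), error = function(e) as.Date(NA))
      as.numeric(d)
    }, numeric(1)), origin = "1970-01-01")
    # as.Date with format silently NA's garbage; also reject re-formatted mismatch
    ok <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == x[!blank]
    if (any(!ok)) {
      bad <- which(!blank)[which(!ok)[1]]
      abort(sprintf("%s: column '%s' row %d: unparseable date '%s' (expected YYYY-MM-DD)",
                    context, col, bad, x[bad]),
            class = "ipfvalid_parse_error")
    }
    out[!blank] <- parsed
  }
  if (!optional && any(blank)) {
    abort(sprintf("%s: column '%s' row %d: date is required but missing",
                  context, col, which(blank)[1]),
          class = "ipfvalid_parse_error")
  }
  out
}

#' Read one of the five linked-EHR tables
#'
#' Reads a header-first delimited text file (the delimiter, tab or comma, is
#' sniffed from the header line), coerces dates from ISO-8601 and validates
#' every structural invariant of the schema: unique patient identifiers in
#' the registry, birth date preceding all other dates, admission before
#' discharge, gap-free 1-based diagnosis positions within an episode (at
#' most 20), and exactly one underlying cause per death record.
#'
#' @param path Path to a delimited text file whose header matches the schema.
#' @param schema One of [ehr_schemas()].
#' @return A tibble, one row per input row, in file order, with date columns
#'   as `Date`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,event_date,code,term",
#'              "p1,2012-05-10,IPF001,idiopathic pulmonary fibrosis"), f)
#' read_ehr_table(f, "events")
#' @export
read_ehr_table <- function(path, schema = ehr_schemas()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ipfvalid_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  spec <- .ehr_schemas[[schema]]
  missing <- setdiff(spec$cols, names(raw))
  if (length(missing)) {
    abort(sprintf("%s: schema '%s' requires column(s) %s", path, schema,
                  paste(sQuote(missing), collapse = ", ")),
          class = "ipfvalid_schema_error")
  }
  raw <- raw[spec$cols]
  for (col in spec$dates) {
    raw[[col]] <- parse_iso_dates(raw[[col]], col,
                                  optional = col %in% spec$optional_dates,
                                  context = path)
  }
  if (schema == "spells") {
    raw$episode_index <- as.integer(raw$episode_index)
    raw$position <- as.integer(raw$position)
  }
  if (schema == "deaths") raw$cause_rank <- as.integer(raw$cause_rank)
  validate_ehr_table(raw, schema, context = path)
}

#' Validate a linked-EHR table against its schema invariants
#'
#' @param x A data frame with the schema's columns (dates already `Date`).
#' @param schema One of [ehr_schemas()].
#' @param context Label used in error messages (usually the file path).
#' @return The validated table as a tibble, invisibly usable in pipes.
#' @export
validate_ehr_table <- function(x, schema = ehr_schemas(), context = "table") {
  schema <- match.arg(schema)
  x <- as_tibble(x)
  fail <- function(row, msg) {
    abort(sprintf("%s (%s): row %d: %s", context, schema, row, msg),
          class = "ipfvalid_integrity_error")
  }
  if (any(is.na(x$patient_id) | x$patient_id == "")) {
    fail(which(is.na(x$patient_id) | x$patient_id == "")[1], "empty patient_id")
  }
  switch(schema,
    registry = {
      dup <- duplicated(x$patient_id)
      if (any(dup)) fail(which(dup)[1], sprintf("duplicate patient_id '%s'", x$patient_id[dup][1]))
      others <- c("registration_start", "last_collection_date",
                  "transfer_out_date", "death_date")
      for (col in others) {
        bad <- !is.na(x[[col]]) & x[[col]] <= x$birth_date
        if (any(bad)) fail(which(bad)[1], sprintf("birth_date not before %s", col))
      }
      bad <- !is.na(x$transfer_out_date) & x$registration_start > x$transfer_out_date
      if (any(bad)) fail(which(bad)[1], "registration_start after transfer_out_date")
      if (!all(x$sex %in% c("male", "female", "unknown"))) {
        bad <- which(!x$sex %in% c("male", "female", "unknown"))[1]
        fail(bad, sprintf("sex must be male/female/unknown, got '%s'", x$sex[bad]))
      }
    },
    events = {
      if (any(x$code == "" | is.na(x$code))) {
        fail(which(x$code == "" | is.na(x$code))[1], "empty clinical code")
      }
    },
    spells = {
      bad <- x$admission_date > x$discharge_date
      if (any(bad)) fail(which(bad)[1], "admission_date after discharge_date")
      if (any(x$position < 1L | x$position > 20L, na.rm = TRUE)) {
        fail(which(x$position < 1L | x$position > 20L)[1],
             "diagnosis position outside 1..20")
      }
      if (nrow(x)) {
        # positions within each episode must be exactly 1..k: after sorting
        # by episode and position they must equal the within-group sequence
        ord <- order(x$patient_id, x$admission_date, x$episode_index, x$position)
        key <- paste(x$patient_id, x$admission_date, x$episode_index,
                     sep = "\r")[ord]
        within <- sequence(rle(key)$lengths)
        bad <- x$position[ord] != within
        if (any(bad)) {
          fail(ord[which(bad)[1]],
               "gap in diagnosis positions (episode positions must be 1..k)")
        }
      }
    },
    deaths = {
      if (any(x$icd10 == "" | is.na(x$icd10))) {
        fail(which(x$icd10 == "" | is.na(x$icd10))[1], "empty cause-of-death code")
      }
      und <- x$patient_id[x$cause_rank == 0L]
      extra <- und[duplicated(und)]
      missing0 <- setdiff(unique(x$patient_id), und)
      if (length(extra) || length(missing0)) {
        bad_id <- c(extra, missing0)[1]
        fail(which(x$patient_id == bad_id)[1],
             "each death record needs exactly one underlying cause (cause_rank 0)")
      }
      dd <- x[!duplicated(paste(x$patient_id, x$death_date, sep = "\r")), ]
      clash <- dd$patient_id[duplicated(dd$patient_id)]
      if (length(clash)) {
        fail(which(x$patient_id == clash[1])[1],
             "conflicting death_date within one patient's death record")
      }
    },
    imaging = {
      if (!all(x$modality %in% c("CT", "XRAY", "MRI", "OTHER"))) {
        bad <- which(!x$modality %in% c("CT", "XRAY", "MRI", "OTHER"))[1]
        fail(bad, sprintf("modality must be CT/XRAY/MRI/OTHER, got '%s'", x$modality[bad]))
      }
      if (!all(x$body_region %in% c("thorax", "other"))) {
        bad <- which(!x$body_region %in% c("thorax", "other"))[1]
        fail(bad, sprintf("body_region must be thorax/other, got '%s'", x$body_region[bad]))
      }
    }
  )
  x
}

#' Write a linked-EHR table as delimited text
#'
#' Dates are written as ISO-8601 and missing optional dates as empty fields,
#' so that a canonical comma-delimited file round-trips byte-identically
#' through [read_ehr_table()] and `write_ehr_table()`.
#'
#' @param x A validated table (see [read_ehr_table()]).
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_ehr_table <- function(x, path, delim = ",") {
  out <- as_tibble(x)
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) {
      v <- format(out[[col]], "%Y-%m-%d")
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  }
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}
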