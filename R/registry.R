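# Registry and event-stream readers, validators and canonical writers.
#
# The registry is one row per patient carrying the administrative dates that
# determine follow-up: registration, an optional data-quality start date (the
# up-to-standard analogue, meaningful only for sources where that metric
# applies), optional transfer-out and death dates, and the practice's last
# data-collection date. The event stream is one row per dated clinical code.

PATIENT_COLUMNS <- c(
  "patient_id", "registration_date", "quality_start_date",
  "transfer_out_date", "death_date", "last_collection_date",
  "sex", "acceptable_quality", "duplicate_excluded"
)
EVENT_COLUMNS <- c("patient_id", "event_date", "code")
SEX_LEVELS <- c("female", "male", "unknown")

parse_flag <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "1", "t", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "0", "f", "no")] <- FALSE
  out
}

read_raw_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(), check.names = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw
}

diagnostic_row <- function(row, field, message) {
  tibble::tibble(row = as.integer(row), field = field, message = message)
}

#' Read a patient registry table
#'
#' Reads and validates `patients.csv`. Rows violating a structural invariant
#' (unparseable date, impossible date ordering, unknown sex code) are rejected
#' with a row-numbered, field-named diagnostic; valid rows are materialised.
#' Empty strings denote absent optional dates.
#'
#' @param path Path to a patients CSV with columns `patient_id`,
#'   `registration_date`, `quality_start_date`, `transfer_out_date`,
#'   `death_date`, `last_collection_date`, `sex`, `acceptable_quality`,
#'   `duplicate_excluded`.
#' @return A list with `patients` (tibble of accepted rows, dates as `Date`)
#'   and `diagnostics` (tibble with `row`, `field`, `message`).
#' @export
read_patient_table <- function(path) {
  raw <- read_raw_csv(path, PATIENT_COLUMNS)
  n <- nrow(raw)
  diags <- list()
  if (n == 0) {
    return(list(patients = empty_patients(), diagnostics = empty_diagnostics()))
  }

  required_date <- c("registration_date", "last_collection_date")
  optional_date <- c("quality_start_date", "transfer_out_date", "death_date")
  dates <- lapply(stats::setNames(nm = c(required_date, optional_date)),
                  function(f) parse_iso_date(raw[[f]]))
  reject <- rep(FALSE, n)

  for (f in c(required_date, optional_date)) {
    blank <- raw[[f]] == ""
    bad <- is.na(dates[[f]]) & !blank
    bad <- bad | (f %in% required_date & blank)
    if (any(bad)) {
      diags[[length(diags) + 1L]] <- diagnostic_row(
        which(bad), f, paste0("unparseable or missing date: '",
                              raw[[f]][bad], "'"))
      reject <- reject | bad
    }
  }

  sex <- tolower(raw$sex)
  bad_sex <- !sex %in% SEX_LEVELS
  if (any(bad_sex)) {
    diags[[length(diags) + 1L]] <- diagnostic_row(
      which(bad_sex), "sex", paste0("unknown sex code: '", raw$sex[bad_sex], "'"))
    reject <- reject | bad_sex
  }
  for (f in c("acceptable_quality", "duplicate_excluded")) {
    flag <- parse_flag(raw[[f]])
    bad <- is.na(flag)
    if (any(bad)) {
      diags[[length(diags) + 1L]] <- diagnostic_row(
        which(bad), f, paste0("not a boolean: '", raw[[f]][bad], "'"))
      reject <- reject | bad
    }
  }

  # ordering invariants, only checkable on rows with parseable dates
  chk <- function(cond, field, message) {
    bad <- !reject & !is.na(cond) & cond
    if (any(bad)) {
      diags[[length(diags) + 1L]] <<- diagnostic_row(which(bad), field, message)
      reject <<- reject | bad
    }
  }
  chk(dates$registration_date > dates$last_collection_date,
      "registration_date", "registration_date after last_collection_date")
  chk(dates$transfer_out_date < dates$registration_date,
      "transfer_out_date", "transfer_out_date before registration_date")
  chk(dates$death_date < dates$registration_date,
      "death_date", "death_date before registration_date")
  chk(dates$quality_start_date < as.Date("1900-01-01"),
      "quality_start_date", "quality_start_date before 1900-01-01")

  keep <- !reject
  patients <- tibble::tibble(
    patient_id = raw$patient_id[keep],
    registration_date = dates$registration_date[keep],
    quality_start_date = dates$quality_start_date[keep],
    transfer_out_date = dates$transfer_out_date[keep],
    death_date = dates$death_date[keep],
    last_collection_date = dates$last_collection_date[keep],
    sex = sex[keep],
    acceptable_quality = parse_flag(raw$acceptable_quality)[keep],
    duplicate_excluded = parse_flag(raw$duplicate_excluded)[keep]
  )
  diagnostics <- if (length(diags)) dplyr::bind_rows(diags) else empty_diagnostics()
  list(patients = patients, diagnostics = dplyr::arrange(diagnostics, row))
}

empty_patients <- function() {
  tibble::tibble(
    patient_id = character(), registration_date = as.Date(character()),
    quality_start_date = as.Date(character()),
    transfer_out_date = as.Date(character()),
    death_date = as.Date(character()),
    last_collection_date = as.Date(character()),
    sex = character(), acceptable_quality = logical(),
    duplicate_excluded = logical()
  )
}

empty_diagnostics <- function() {
  tibble::tibble(row = integer(), field = character(), message = character())
}

#' Read a clinical event table
#'
#' Reads and validates `events.csv` (`patient_id`, `event_date`, `code`).
#' Rows with an unparseable date or an empty code are rejected with a
#' diagnostic. Events referencing a patient id not in `known_ids`, or dated
#' implausibly (before 1900 or after `latest_collection`), are retained but
#' flagged rather than dropped.
#'
#' @param path Path to the events CSV.
#' @param known_ids Optional character vector of registry patient ids.
#' @param latest_collection Optional `Date`; events after it are flagged.
#' @return A list with `events` (tibble: `patient_id`, `event_date`, `code`,
#'   `flag` — `NA` when unremarkable) and `diagnostics`.
#' @export
read_event_table <- function(path, known_ids = NULL, latest_collection = NULL) {
  raw <- read_raw_csv(path, EVENT_COLUMNS)
  n <- nrow(raw)
  if (n == 0) {
    return(list(events = empty_events(), diagnostics = empty_diagnostics()))
  }
  diags <- list()
  dates <- parse_iso_date(raw$event_date)
  reject <- is.na(dates)
  if (any(reject)) {
    diags[[length(diags) + 1L]] <- diagnostic_row(
      which(reject), "event_date",
      paste0("unparseable or missing date: '", raw$event_date[reject], "'"))
  }
  bad_code <- !reject & raw$code == ""
  if (any(bad_code)) {
    diags[[length(diags) + 1L]] <- diagnostic_row(
      which(bad_code), "code", "empty clinical code")
    reject <- reject | bad_code
  }

  keep <- !reject
  events <- tibble::tibble(
    patient_id = raw$patient_id[keep],
    event_date = dates[keep],
    code = raw$code[keep],
    flag = NA_character_
  )
  if (!is.null(known_ids)) {
    orphan <- !events$patient_id %in% known_ids
    events$flag[orphan] <- "unknown_patient"
  }
  implausible <- events$event_date < as.Date("1900-01-01")
  if (!is.null(latest_collection) && !is.na(latest_collection)) {
    implausible <- implausible | events$event_date > latest_collection
  }
  events$flag[implausible & is.na(events$flag)] <- "implausible_date"
  diagnostics <- if (length(diags)) dplyr::bind_rows(diags) else empty_diagnostics()
  list(events = events, diagnostics = dplyr::arrange(diagnostics, row))
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), event_date = as.Date(character()),
                 code = character(), flag = character())
}

#' Load a registry and its event stream together
#'
#' Convenience wrapper over [read_patient_table()] and [read_event_table()]
#' that cross-references the two files: events with a patient id absent from
#' the registry are flagged, and events after the registry's latest
#' last-collection date are flagged as implausible.
#'
#' @param patients_path,events_path CSV paths.
#' @return A list with `patients`, `events`, and `diagnostics` (both files'
#'   diagnostics, with a `file` column).
#' @export
load_registry <- function(patients_path, events_path) {
  p <- read_patient_table(patients_path)
  latest <- if (nrow(p$patients)) max(p$patients$last_collection_date) else NULL
  e <- read_event_table(events_path, known_ids = p$patients$patient_id,
                        latest_collection = latest)
  diagnostics <- dplyr::bind_rows(
    dplyr::mutate(p$diagnostics, file = "patients", .before = 1),
    dplyr::mutate(e$diagnostics, file = "events", .before = 1)
  )
  list(patients = p$patients, events = e$events, diagnostics = diagnostics)
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
fmt_flagcol <- function(x) ifelse(x, "true", "false")

#' Write a registry in canonical form
#'
#' Writes `patients` and `events` back to CSV in the canonical dialect the
#' readers accept: ISO-8601 dates, empty string for absent values, lowercase
#' `true`/`false` booleans, no quoting. Reading a canonical file and writing
#' it again reproduces the file byte for byte.
#'
#' @param patients,events Tibbles as returned by [load_registry()].
#' @param patients_path,events_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_registry <- function(patients, events, patients_path, events_path) {
  pout <- data.frame(
    patient_id = patients$patient_id,
    registration_date = fmt_date(patients$registration_date),
    quality_start_date = fmt_date(patients$quality_start_date),
    transfer_out_date = fmt_date(patients$transfer_out_date),
    death_date = fmt_date(patients$death_date),
    last_collection_date = fmt_date(patients$last_collection_date),
    sex = patients$sex,
    acceptable_quality = fmt_flagcol(patients$acceptable_quality),
    duplicate_excluded = fmt_flagcol(patients$duplicate_excluded),
    check.names = FALSE
  )
  eout <- data.frame(
    patient_id = events$patient_id,
    event_date = fmt_date(events$event_date),
    code = events$code,
    check.names = FALSE
  )
  utils::write.csv(pout, patients_path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  utils::write.csv(eout, events_path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(c(patients_path, events_path))
}
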