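# Follow-up derivation, cohort selection and exposure episodes.
#
# Follow-up starts at registration (or, where a data-quality start date
# applies, at the later of the two) and ends at the earliest of transfer-out,
# death, and the practice's last data-collection date. Patients need at least
# one day of follow-up; unacceptable-quality and duplicate-flagged patients
# are excluded with a named reason.

#' Derive per-patient follow-up windows
#'
#' @param patients Patient tibble from [read_patient_table()].
#' @param uts_applies If `TRUE`, follow-up cannot start before the patient's
#'   `quality_start_date` (the up-to-standard rule); if `FALSE` the quality
#'   date is ignored, as for sources without that metric.
#' @return A list with `followup` (tibble: `patient_id`, `registration_date`,
#'   `fu_start`, `fu_end` for retained patients) and `exclusions` (tibble:
#'   `patient_id`, `reason` in `"unacceptable quality"`, `"duplicate"`,
#'   `"no follow-up"`).
#' @export
derive_follow_up <- function(patients, uts_applies = FALSE) {
  fu_start <- if (uts_applies) {
    date_max(patients$registration_date, patients$quality_start_date)
  } else {
    patients$registration_date
  }
  fu_end <- date_min(patients$transfer_out_date, patients$death_date,
                     patients$last_collection_date)
  reason <- rep(NA_character_, nrow(patients))
  reason[fu_end < fu_start] <- "no follow-up"
  reason[patients$duplicate_excluded] <- "duplicate"
  reason[!patients$acceptable_quality] <- "unacceptable quality"
  keep <- is.na(reason)
  list(
    followup = tibble::tibble(
      patient_id = patients$patient_id[keep],
      registration_date = patients$registration_date[keep],
      fu_start = fu_start[keep],
      fu_end = fu_end[keep]
    ),
    exclusions = tibble::tibble(
      patient_id = patients$patient_id[!keep],
      reason = reason[!keep]
    )
  )
}

# Matching events for retained patients: exact code match, same-day
# duplicates collapsed, sorted by patient then date.
matching_events <- function(events, definition, followup) {
  events |>
    dplyr::filter(.data$code %in% definition$codes,
                  .data$patient_id %in% followup$patient_id) |>
    dplyr::distinct(.data$patient_id, .data$event_date) |>
    dplyr::arrange(.data$patient_id, .data$event_date)
}

#' Select the disease cohort
#'
#' A patient enters the disease cohort if they have at least one event whose
#' code is in the definition's code list (exact string match). The
#' presentation date is the earliest such event — even when it falls before
#' follow-up start: such a patient is prevalent from registration onward but
#' can never be incident.
#'
#' @param events Event tibble.
#' @param definition A [disease_definition()].
#' @param followup Follow-up list or tibble from [derive_follow_up()].
#' @return Tibble with `patient_id` and `presentation_date`.
#' @export
select_disease_cohort <- function(events, definition, followup) {
  if (is.list(followup) && !is.data.frame(followup)) followup <- followup$followup
  matching_events(events, definition, followup) |>
    dplyr::summarise(presentation_date = min(.data$event_date),
                     .by = "patient_id")
}

# Merge sorted intervals given as parallel onset/end vectors (inclusive
# ends); overlapping or abutting (gap 0) intervals coalesce.
merge_intervals <- function(onset, end) {
  if (length(onset) == 0) {
    return(list(onset = as.Date(character()), end = as.Date(character())))
  }
  o <- order(onset, end)
  onset <- onset[o]; end <- end[o]
  keep_onset <- onset[1]; keep_end <- end[1]
  out_onset <- list(); out_end <- list()
  for (i in seq_along(onset)[-1]) {
    if (as.integer(onset[i]) <= as.integer(keep_end) + 1L) {
      keep_end <- max(keep_end, end[i])
    } else {
      out_onset[[length(out_onset) + 1L]] <- keep_onset
      out_end[[length(out_end) + 1L]] <- keep_end
      keep_onset <- onset[i]; keep_end <- end[i]
    }
  }
  out_onset[[length(out_onset) + 1L]] <- keep_onset
  out_end[[length(out_end) + 1L]] <- keep_end
  list(onset = as.Date(vapply(out_onset, as.integer, 1L), origin = "1970-01-01"),
       end = as.Date(vapply(out_end, as.integer, 1L), origin = "1970-01-01"))
}

#' Build exposure episodes
#'
#' Turns each cohort patient's matching events into intervals of disease
#' exposure. For a lifelong disease there is a single episode from the
#' presentation date to the end of follow-up. Otherwise each event opens an
#' episode lasting `expected_duration_days`; overlapping or abutting episodes
#' merge into one continuous illness, and episodes are clipped at the end of
#' follow-up (an episode may begin before follow-up start, but a patient
#' cannot be observed exposed after follow-up ends). Episodes that would
#' start after follow-up end are dropped.
#'
#' Episode `end` is the last included day (internal arithmetic is half-open).
#'
#' @inheritParams select_disease_cohort
#' @return Tibble with `patient_id`, `onset`, `end`, non-overlapping within
#'   patient.
#' @export
build_exposure_episodes <- function(events, definition, followup) {
  if (is.list(followup) && !is.data.frame(followup)) followup <- followup$followup
  ev <- matching_events(events, definition, followup)
  if (nrow(ev) == 0) {
    return(tibble::tibble(patient_id = character(),
                          onset = as.Date(character()),
                          end = as.Date(character())))
  }
  fu_end <- stats::setNames(followup$fu_end, followup$patient_id)
  if (is_lifelong(definition)) {
    ep <- ev |>
      dplyr::summarise(onset = min(.data$event_date), .by = "patient_id")
    ep$end <- as.Date(unname(fu_end[ep$patient_id]), origin = "1970-01-01")
  } else {
    dur <- definition$expected_duration_days
    ep <- ev |>
      dplyr::mutate(onset = .data$event_date,
                    end = .data$event_date + dur - 1L) |>
      dplyr::reframe(merge_intervals(.data$onset, .data$end) |>
                       tibble::as_tibble(),
                     .by = "patient_id")
    ep$end <- date_min(ep$end, as.Date(unname(fu_end[ep$patient_id]),
                                       origin = "1970-01-01"))
  }
  ep <- ep[as.integer(ep$onset) <= as.integer(ep$end), , drop = FALSE]
  tibble::as_tibble(ep[c("patient_id", "onset", "end")])
}

#' Write an episode dump
#'
#' @param episodes Episode tibble from [build_exposure_episodes()].
#' @param path Output CSV path (`patient_id,onset,end`, inclusive end).
#' @return Invisibly, `path`.
#' @export
write_episodes <- function(episodes, path) {
  out <- data.frame(patient_id = episodes$patient_id,
                    onset = fmt_date(episodes$onset),
                    end = fmt_date(episodes$end))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
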