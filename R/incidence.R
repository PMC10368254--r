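# Annual incidence with calendar-year person-time denominators.
#
# An event is incident when it falls inside follow-up, at least 90 days after
# registration (the wash-in, during which a record may reflect pre-existing
# disease), and — for a lifelong disease — is the patient's first-ever
# matching record, or — for recurrent diseases — has no matching record in
# the preceding expected-duration window.

WASHIN_DAYS <- 90L
DAYS_PER_YEAR <- 365.25
SCALE_CHOICES <- 10^(2:6)

#' Identify incident events
#'
#' @param events Event tibble.
#' @param definition A [disease_definition()].
#' @param followup Result of [derive_follow_up()] (list or its `followup`
#'   tibble).
#' @param washin_days Post-registration wash-in in days; an event is only
#'   incident on or after `registration_date + washin_days`. Default 90.
#' @return Tibble with `patient_id` and `incident_date`. For a lifelong
#'   disease each patient has at most one row; for recurrent diseases
#'   consecutive incident dates are more than `expected_duration_days` apart.
#' @export
identify_incident_events <- function(events, definition, followup,
                                     washin_days = WASHIN_DAYS) {
  if (is.list(followup) && !is.data.frame(followup)) followup <- followup$followup
  ev <- matching_events(events, definition, followup) |>
    dplyr::inner_join(followup, by = "patient_id")
  if (nrow(ev) == 0) {
    return(tibble::tibble(patient_id = character(),
                          incident_date = as.Date(character())))
  }
  ev <- ev |> dplyr::mutate(
    first_ever = .data$event_date == min(.data$event_date),
    gap = as.integer(.data$event_date - dplyr::lag(.data$event_date)),
    .by = "patient_id"
  )
  novel <- if (is_lifelong(definition)) {
    ev$first_ever
  } else {
    # no matching record in [t - duration, t): the nearest candidate is the
    # immediately preceding distinct event date
    is.na(ev$gap) | ev$gap > definition$expected_duration_days
  }
  ok <- novel &
    ev$event_date >= ev$fu_start & ev$event_date <= ev$fu_end &
    ev$event_date >= ev$registration_date + washin_days
  tibble::tibble(patient_id = ev$patient_id[ok],
                 incident_date = ev$event_date[ok])
}

# Denominator eligibility: at least `washin_days` days' registration,
# measured on the registration-to-follow-up-end span.
denominator_eligible <- function(followup, washin_days = WASHIN_DAYS) {
  followup[as.integer(followup$fu_end) -
             as.integer(followup$registration_date) >= washin_days, ,
           drop = FALSE]
}

#' Person-time at risk in one calendar year
#'
#' For each denominator-eligible patient (at least 90 days' registration),
#' at-risk time in a year runs from the latest of 1 January, follow-up start,
#' and registration plus the wash-in, to the earliest of 31 December
#' (inclusive) and follow-up end. For a lifelong disease the patient is
#' additionally censored at disease onset (the presentation date). For
#' recurrent diseases exposure windows are not at-risk: each episode's days
#' are subtracted, and the patient re-enters the risk set when the episode
#' ends.
#'
#' @param year Calendar year.
#' @param definition A [disease_definition()].
#' @param followup Result of [derive_follow_up()].
#' @param episodes Episode tibble from [build_exposure_episodes()] for the
#'   same disease (used for censoring; may be empty).
#' @param washin_days Wash-in length in days, default 90.
#' @param by_patient If `TRUE`, return the per-patient contributions instead
#'   of their sum.
#' @return Total person-days (integer scalar), or a tibble of `patient_id`
#'   and `person_days` when `by_patient = TRUE`.
#' @export
person_time_by_year <- function(year, definition, followup, episodes,
                                washin_days = WASHIN_DAYS,
                                by_patient = FALSE) {
  if (is.list(followup) && !is.data.frame(followup)) followup <- followup$followup
  fu <- denominator_eligible(followup, washin_days)
  if (nrow(fu) == 0) {
    return(if (by_patient) {
      tibble::tibble(patient_id = character(), person_days = integer())
    } else 0L)
  }
  a <- date_max(year_start(year), fu$fu_start,
                fu$registration_date + washin_days)
  b_excl <- date_min(year_start(year + 1), fu$fu_end + 1L)
  if (is_lifelong(definition) && nrow(episodes) > 0) {
    onset <- stats::setNames(as.integer(episodes$onset), episodes$patient_id)
    pt_onset <- onset[fu$patient_id]
    b_excl <- as.Date(ifelse(is.na(pt_onset), as.integer(b_excl),
                             pmin(as.integer(b_excl), pt_onset)),
                      origin = "1970-01-01")
  }
  days <- days_between(a, b_excl)
  if (!is_lifelong(definition) && nrow(episodes) > 0) {
    # subtract exposed days: episodes are disjoint within patient, so the
    # per-episode overlaps with [a, b_excl) sum without double counting
    bounds <- tibble::tibble(patient_id = fu$patient_id,
                             a = as.integer(a), b = as.integer(b_excl))
    exposed <- episodes |>
      dplyr::inner_join(bounds, by = "patient_id") |>
      dplyr::mutate(overlap = pmax(0L, pmin(as.integer(.data$end) + 1L, .data$b) -
                                     pmax(as.integer(.data$onset), .data$a))) |>
      dplyr::summarise(exposed = sum(.data$overlap), .by = "patient_id")
    idx <- match(fu$patient_id, exposed$patient_id)
    days <- days - ifelse(is.na(idx), 0L, exposed$exposed[idx])
  }
  if (by_patient) {
    return(tibble::tibble(patient_id = fu$patient_id,
                          person_days = as.integer(days)))
  }
  as.integer(sum(days))
}

# Smallest power of ten in 10^2..10^6 that lifts the period-average rate to
# at least 1; falls back to 10^6 for very rare outcomes.
auto_scale <- function(numerators, denominators) {
  num <- sum(numerators, na.rm = TRUE)
  den <- sum(denominators, na.rm = TRUE)
  if (den <= 0 || num == 0) return(SCALE_CHOICES[length(SCALE_CHOICES)])
  avg <- num / den
  ok <- SCALE_CHOICES[avg * SCALE_CHOICES >= 1]
  if (length(ok) == 0) SCALE_CHOICES[length(SCALE_CHOICES)] else ok[1]
}

#' Annual incidence rates
#'
#' Runs the full incidence pipeline for one disease: derives follow-up,
#' selects the cohort, builds exposure episodes, identifies incident events,
#' and for each calendar year of the observation window divides incident
#' cases by person-years at risk (person-days / 365.25).
#'
#' @param patients Patient tibble from [read_patient_table()].
#' @param events Event tibble.
#' @param definition A [disease_definition()].
#' @param window An [observation_window()].
#' @param scale `"auto"` (smallest power of ten in 10^2..10^6 making the
#'   period-average rate at least 1) or an explicit power of ten; rates are
#'   reported per `scale` person-years.
#' @param uts_applies Passed to [derive_follow_up()].
#' @param washin_days Wash-in length in days, default 90.
#' @return Tibble with `disease`, `year`, `numerator`, `person_years`,
#'   `rate`, `scale`. Years with zero person-time report `rate = NA`.
#' @export
annual_incidence <- function(patients, events, definition,
                             window = observation_window(),
                             scale = "auto", uts_applies = FALSE,
                             washin_days = WASHIN_DAYS) {
  fu <- derive_follow_up(patients, uts_applies)$followup
  episodes <- build_exposure_episodes(events, definition, fu)
  incident <- identify_incident_events(events, definition, fu, washin_days)
  years <- window_years(window)
  incident_years <- as.integer(format(incident$incident_date, "%Y"))
  numerator <- vapply(years, function(y) sum(incident_years == y), 1L)
  person_days <- vapply(years, function(y) {
    person_time_by_year(y, definition, fu, episodes, washin_days)
  }, 1L)
  person_years <- person_days / DAYS_PER_YEAR
  scale <- if (identical(scale, "auto")) {
    auto_scale(numerator, person_years)
  } else {
    as.numeric(scale)
  }
  rate <- ifelse(person_years > 0, numerator / person_years * scale, NA_real_)
  tibble::tibble(disease = definition$name, year = years,
                 numerator = numerator, person_years = person_years,
                 rate = rate, scale = scale)
}
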