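# Point and period prevalence with mid-year (30 June) denominators.
#
# Point prevalence (chronic / non-lifelong diseases): a patient counts in
# year Y if both their follow-up and an exposure episode cover 30 June of Y.
# Period prevalence (acute diseases): a patient counts if follow-up and an
# episode each overlap any part of Y; the denominator is nonetheless the
# mid-year population, which can place a patient in the numerator but not
# the denominator — such patients are surfaced in a consistency report, not
# silently reassigned. The 90-day wash-in applies to incidence only, never
# to prevalence denominators.

covers <- function(start, end, date) {
  as.integer(start) <= as.integer(date) & as.integer(date) <= as.integer(end)
}

overlaps_year <- function(start, end, year) {
  as.integer(start) <= as.integer(year_end(year)) &
    as.integer(end) >= as.integer(year_start(year))
}

prevalence_estimate <- function(definition, year, type, numerator, population,
                                scale) {
  numerator <- unname(numerator)
  population <- unname(population)
  rate <- ifelse(population > 0, numerator / population * scale, NA_real_)
  tibble::tibble(disease = definition$name, year = year,
                 prevalence_type = type,
                 numerator = numerator, population = population,
                 rate = rate, scale = scale)
}

#' Point prevalence at mid-year
#'
#' @param years Integer vector of calendar years.
#' @param episodes Episode tibble from [build_exposure_episodes()].
#' @param followup Result of [derive_follow_up()] (list or tibble) covering
#'   the whole eligible population, cases and non-cases alike.
#' @param definition The [disease_definition()] (labels the output).
#' @param scale Persons per which the rate is expressed; `"auto"` picks the
#'   smallest power of ten in 10^2..10^6 making the period-average rate at
#'   least 1.
#' @return Tibble with `disease`, `year`, `prevalence_type`, `numerator`,
#'   `population`, `rate`, `scale`.
#' @export
point_prevalence <- function(years, episodes, followup, definition,
                             scale = "auto") {
  if (is.list(followup) && !is.data.frame(followup)) followup <- followup$followup
  counts <- vapply(years, function(y) {
    mid <- midyear(y)
    in_fu <- covers(followup$fu_start, followup$fu_end, mid)
    exposed_ids <- unique(
      episodes$patient_id[covers(episodes$onset, episodes$end, mid)])
    c(numerator = sum(in_fu & followup$patient_id %in% exposed_ids),
      population = sum(in_fu))
  }, c(numerator = 1L, population = 1L))
  scale <- resolve_prevalence_scale(scale, counts["numerator", ],
                                    counts["population", ])
  prevalence_estimate(definition, years, "point",
                      counts["numerator", ], counts["population", ], scale)
}

#' Period prevalence over calendar years
#'
#' Numerator: patients whose follow-up and some exposure episode each overlap
#' any part of the year (one count per patient per year, however many
#' episodes). Denominator: patients whose follow-up covers 30 June of the
#' year. The accompanying consistency report lists patients counted in a
#' year's numerator whose follow-up misses that mid-year point.
#'
#' @inheritParams point_prevalence
#' @return A list with `estimates` (same shape as [point_prevalence()], with
#'   `prevalence_type = "period"`) and `consistency` (tibble: `year`,
#'   `patient_id` for numerator-without-denominator patients).
#' @export
period_prevalence <- function(years, episodes, followup, definition,
                              scale = "auto") {
  if (is.list(followup) && !is.data.frame(followup)) followup <- followup$followup
  anomalies <- list()
  counts <- vapply(years, function(y) {
    mid <- midyear(y)
    fu_in_year <- overlaps_year(followup$fu_start, followup$fu_end, y)
    fu_at_mid <- covers(followup$fu_start, followup$fu_end, mid)
    exposed_ids <- unique(
      episodes$patient_id[overlaps_year(episodes$onset, episodes$end, y)])
    in_num <- fu_in_year & followup$patient_id %in% exposed_ids
    odd <- in_num & !fu_at_mid
    if (any(odd)) {
      anomalies[[length(anomalies) + 1L]] <<- tibble::tibble(
        year = y, patient_id = followup$patient_id[odd])
    }
    c(numerator = sum(in_num), population = sum(fu_at_mid))
  }, c(numerator = 1L, population = 1L))
  scale <- resolve_prevalence_scale(scale, counts["numerator", ],
                                    counts["population", ])
  list(
    estimates = prevalence_estimate(definition, years, "period",
                                    counts["numerator", ],
                                    counts["population", ], scale),
    consistency = if (length(anomalies)) dplyr::bind_rows(anomalies) else
      tibble::tibble(year = integer(), patient_id = character())
  )
}

resolve_prevalence_scale <- function(scale, numerators, populations) {
  if (identical(scale, "auto")) auto_scale(numerators, populations)
  else as.numeric(scale)
}

#' Annual prevalence
#'
#' Full prevalence pipeline for one disease: derives follow-up, builds
#' exposure episodes, and computes point prevalence (chronic and non-lifelong
#' diseases) or period prevalence (acute diseases) across the observation
#' window. The type can be overridden.
#'
#' @inheritParams annual_incidence
#' @param type `"auto"` (period for acute, point otherwise), `"point"` or
#'   `"period"`.
#' @return A list with `estimates` and `consistency` (empty for point
#'   prevalence).
#' @export
annual_prevalence <- function(patients, events, definition,
                              window = observation_window(),
                              type = c("auto", "point", "period"),
                              scale = "auto", uts_applies = FALSE) {
  type <- match.arg(type)
  if (type == "auto") {
    type <- if (definition$chronicity == "acute") "period" else "point"
  }
  fu <- derive_follow_up(patients, uts_applies)$followup
  episodes <- build_exposure_episodes(events, definition, fu)
  years <- window_years(window)
  if (type == "point") {
    list(estimates = point_prevalence(years, episodes, fu, definition, scale),
         consistency = tibble::tibble(year = integer(),
                                      patient_id = character()))
  } else {
    period_prevalence(years, episodes, fu, definition, scale)
  }
}
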