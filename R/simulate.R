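# Synthetic patient registries with known ground truth.
#
# Patients register uniformly over a configurable span (which may start
# before the observation window, as real practice lists do). From each
# patient's registration, independent exponential clocks run for transfer
# out, death, and disease onset; competing risks resolve by the minimum.
# Events are recorded only while the patient's record is live. For acute
# diseases, the next onset is drawn after the current episode ends, so
# inter-event gaps are at least one expected duration by construction.

#' Simulation configuration
#'
#' Hazards are per person-year and converted internally with 365.25 days per
#' year. The defaults emulate a UK primary-care registry over 2004-2020:
#' registration staggered from ten years before the window opens, modest
#' practice turnover (5%/year transfer out) and background mortality
#' (1%/year).
#'
#' @param n_patients Number of patients.
#' @param window [observation_window()] the registry serves.
#' @param entry_start,entry_end Registration dates are uniform over this
#'   span; defaults: ten years before the window start, to the window end.
#' @param exit_hazard,death_hazard,onset_hazard Constant hazards per
#'   person-year for transfer out, death, and first disease onset.
#' @param chronicity,expected_duration_days Disease settings, as in
#'   [disease_definition()].
#' @param recurrence_hazard For acute diseases, hazard per person-year of a
#'   new onset once the previous episode has ended.
#' @param code Clinical code written for every disease event.
#' @param seed Mandatory integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients,
                              window = observation_window(),
                              entry_start = window$start_date - 3653L,
                              entry_end = window$end_date,
                              exit_hazard = 0.05,
                              death_hazard = 0.01,
                              onset_hazard = 0.01,
                              chronicity = "lifelong",
                              expected_duration_days = NULL,
                              recurrence_hazard = 0,
                              code = "D1",
                              seed) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  hazards <- c(exit_hazard, death_hazard, onset_hazard, recurrence_hazard)
  stopifnot(n_patients >= 1, all(is.finite(hazards)), all(hazards >= 0))
  # validate chronicity/duration pairing by building a throwaway definition
  disease_definition("synthetic", chronicity, expected_duration_days,
                     codes = code)
  structure(list(
    n_patients = as.integer(n_patients), window = window,
    entry_start = as.Date(entry_start), entry_end = as.Date(entry_end),
    exit_hazard = exit_hazard, death_hazard = death_hazard,
    onset_hazard = onset_hazard, chronicity = chronicity,
    expected_duration_days = expected_duration_days,
    recurrence_hazard = recurrence_hazard, code = code,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Disease definition matching a simulation config
#'
#' @param config A [simulation_config()].
#' @param name Disease name for the definition.
#' @return A [disease_definition()] with the config's chronicity, duration
#'   and event code.
#' @export
simulated_disease <- function(config, name = "synthetic") {
  disease_definition(name, config$chronicity, config$expected_duration_days,
                     codes = config$code)
}

# Exponential waiting time in whole days; rate is per person-year.
rexp_days <- function(n, hazard_py) {
  if (hazard_py <= 0) return(rep(Inf, n))
  ceiling(stats::rexp(n, rate = hazard_py / DAYS_PER_YEAR))
}

#' Simulate a registry and event stream
#'
#' Fully reproducible from the config seed: identical config yields
#' byte-identical tables. The returned ground truth carries the configured
#' onset hazard together with a Monte-Carlo standard error for the pooled
#' incidence estimate implied by the realised at-risk time, so estimator
#' recovery can be judged on the simulation's own scale.
#'
#' @param config A [simulation_config()].
#' @return A list with `patients` (registry tibble), `events` (event
#'   tibble) and `truth` (list: `incidence` per person-year,
#'   `incidence_se`, `at_risk_person_years`).
#' @export
simulate_registry <- function(config) {
  set.seed(config$seed)
  n <- config$n_patients
  span <- as.integer(config$entry_end) - as.integer(config$entry_start)
  registration <- config$entry_start +
    floor(stats::runif(n) * (span + 1L))
  last_collection <- rep(config$window$end_date, n)

  exit_days <- rexp_days(n, config$exit_hazard)
  death_days <- rexp_days(n, config$death_hazard)
  reg_int <- as.integer(registration)
  lc_int <- as.integer(last_collection)
  # end of the live record, as a day number (never past last collection)
  record_end <- pmin(reg_int + pmin(exit_days, death_days), lc_int)
  transfer_out <- as.Date(ifelse(
    is.finite(exit_days) & exit_days < death_days &
      reg_int + exit_days <= lc_int,
    reg_int + exit_days, NA_real_), origin = "1970-01-01")
  death <- as.Date(ifelse(
    is.finite(death_days) & death_days <= exit_days &
      reg_int + death_days <= lc_int,
    reg_int + death_days, NA_real_), origin = "1970-01-01")

  onset_days <- rexp_days(n, config$onset_hazard)
  first_onset <- reg_int + onset_days

  ev <- list()
  at_risk_days <- pmin(onset_days, record_end - reg_int)
  recorded <- is.finite(first_onset) & first_onset <= record_end
  if (any(recorded)) {
    ev[[1]] <- tibble::tibble(
      patient_id = sprintf("P%06d", which(recorded)),
      event_date = as.Date(first_onset[recorded], origin = "1970-01-01"),
      code = config$code)
  }
  if (config$chronicity != "lifelong" && config$recurrence_hazard > 0) {
    # recurrences: next onset drawn after the previous episode's end
    dur <- config$expected_duration_days
    active <- which(recorded)
    current <- first_onset[active]
    while (length(active) > 0) {
      gap <- rexp_days(length(active), config$recurrence_hazard)
      nxt <- current + dur + gap
      live <- is.finite(nxt) & nxt <= record_end[active]
      active <- active[live]; nxt <- nxt[live]
      if (length(active) == 0) break
      ev[[length(ev) + 1L]] <- tibble::tibble(
        patient_id = sprintf("P%06d", active),
        event_date = as.Date(nxt, origin = "1970-01-01"),
        code = config$code)
      current <- nxt
    }
  }
  events <- if (length(ev)) {
    dplyr::arrange(dplyr::bind_rows(ev), .data$patient_id, .data$event_date)
  } else {
    tibble::tibble(patient_id = character(),
                   event_date = as.Date(character()), code = character())
  }
  events$flag <- NA_character_

  patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    registration_date = registration,
    quality_start_date = as.Date(NA),
    transfer_out_date = transfer_out,
    death_date = death,
    last_collection_date = last_collection,
    sex = c("female", "male")[1L + (stats::runif(n) < 0.5)],
    acceptable_quality = TRUE,
    duplicate_excluded = FALSE
  )

  # at-risk time on the estimator's scale: clipped to the observation
  # window and excluding the 90-day wash-in
  a <- pmax(reg_int + WASHIN_DAYS, as.integer(config$window$start_date))
  b <- pmin(reg_int + at_risk_days, as.integer(config$window$end_date) + 1)
  at_risk_py <- sum(pmax(0, b - a)) / DAYS_PER_YEAR
  expected_cases <- config$onset_hazard * at_risk_py
  truth <- list(
    incidence = config$onset_hazard,
    incidence_se = if (at_risk_py > 0 && expected_cases > 0)
      sqrt(expected_cases) / at_risk_py else NA_real_,
    at_risk_person_years = at_risk_py
  )
  list(patients = patients, events = events, truth = truth)
}

#' Monte-Carlo ground-truth prevalence
#'
#' Estimates the true mid-year point prevalence (or within-year period
#' prevalence) of the simulated disease by running a large independent
#' replicate of the same generative process and reading exposure straight
#' off the simulated latent histories — no estimator code is involved.
#'
#' @param config A [simulation_config()] (its seed is offset so the replicate
#'   is independent of the analysis dataset).
#' @param years Calendar years to evaluate.
#' @param n_rep Replicate size, default 200000.
#' @param type `"point"` or `"period"`.
#' @return Tibble with `year`, `prevalence` (proportion), `se`, `n` (mid-year
#'   population of the replicate).
#' @export
prevalence_truth_mc <- function(config, years, n_rep = 2e5,
                                type = c("point", "period")) {
  type <- match.arg(type)
  big <- config
  big$n_patients <- as.integer(n_rep)
  big$seed <- (config$seed + 499979L) %% .Machine$integer.max
  sim <- simulate_registry(big)
  p <- sim$patients
  fu_start <- as.integer(p$registration_date)
  fu_end <- as.integer(date_min(p$transfer_out_date, p$death_date,
                                p$last_collection_date))
  ev_date <- as.integer(sim$events$event_date)
  ev_pid <- sim$events$patient_id
  lifelong <- config$chronicity == "lifelong"
  dur <- if (lifelong) NA_integer_ else config$expected_duration_days
  ep_end <- if (lifelong) {
    # exposed from first event to end of follow-up
    unname(fu_end[match(ev_pid, p$patient_id)])
  } else {
    pmin(ev_date + dur - 1L, unname(fu_end[match(ev_pid, p$patient_id)]))
  }
  out <- lapply(years, function(y) {
    mid <- as.integer(midyear(y))
    ys <- as.integer(year_start(y)); ye <- as.integer(year_end(y))
    denom <- fu_start <= mid & mid <= fu_end
    if (type == "point") {
      exposed <- unique(ev_pid[ev_date <= mid & ep_end >= mid])
      num <- sum(denom & p$patient_id %in% exposed)
    } else {
      exposed <- unique(ev_pid[ev_date <= ye & ep_end >= ys])
      num <- sum(fu_start <= ye & fu_end >= ys & p$patient_id %in% exposed)
    }
    nd <- sum(denom)
    prop <- if (nd > 0) num / nd else NA_real_
    tibble::tibble(year = y, prevalence = prop,
                   se = if (nd > 0) max(sqrt(prop * (1 - prop) / nd),
                                        sqrt(0.25 / nd^1.5)) else NA_real_,
                   n = nd)
  })
  dplyr::bind_rows(out)
}
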