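# Bundled worked datasets and deterministic test fixtures.

#' Published prevalence comparison pairs
#'
#' Paired most-recent-year prevalence estimates for twelve chronic or
#' long-duration conditions: for each condition, the value reported by a
#' peer-reviewed UK primary-care database study and the value produced for
#' the same year by an automated analytics pipeline over the same kind of
#' source data. Each pair is expressed on the study's own printed
#' denominator scale (persons per `scale` population), so the two columns of
#' a row are directly comparable but rows are not on a common scale.
#'
#' This is the canonical demonstration input for [concordance()]: agreement
#' between the two columns is what the concordance module was built to
#' quantify.
#'
#' @return Tibble with `label` (condition), `year`, `scale` (denominator
#'   persons), `reference` (published value) and `candidate` (automated
#'   estimate), both on the printed scale.
#' @export
reference_prevalence_pairs <- function() {
  tibble::tribble(
    ~label,                          ~year, ~scale,  ~reference, ~candidate,
    "charcot_marie_tooth",           2019,  1e5,     29.5,       27.7,
    "diabetic_retinopathy",          2014,  1e3,     22.01,      20.03,
    "guillain_barre",                2019,  1e5,     40.1,       40.0,
    "idiopathic_pulmonary_fibrosis", 2012,  1e5,     10.57,      10.32,
    "inflammatory_myopathy",         2019,  1e5,     25.0,       24.5,
    "lennox_gastaut",                2017,  1e4,     0.289,      0.167,
    "motor_neurone_disease",         2019,  1e5,     12.6,       12.3,
    "muscular_dystrophy",            2019,  1e5,     29.5,       31.1,
    "myasthenia_gravis",             2019,  1e5,     33.7,       32.9,
    "optic_neuritis",                2018,  1e5,     114.8,      98.4,
    "osteoarthritis",                2017,  1e2,     10.77,      10.61,
    "systemic_sclerosis",            2013,  1e6,     307,        305
  )
}

FIXTURE_NAMES <- c("published_prevalence_pairs", "washin_boundary",
                   "period_asymmetry")

#' Write a named worked fixture
#'
#' Deterministic file bundles used by the test suite and the tutorial:
#'
#' * `"published_prevalence_pairs"`: the [reference_prevalence_pairs()]
#'   table as `pairs.csv` plus `reference.csv`/`candidate.csv` in the
#'   `label,value` layout the concordance CLI reads.
#' * `"washin_boundary"`: a two-patient registry in which one patient's only
#'   disease record falls 89 days after registration (inside the wash-in,
#'   not incident) and the other's falls exactly 90 days after (incident);
#'   with `patients.csv`, `events.csv`, `disease.json`.
#' * `"period_asymmetry"`: an acute-disease registry containing a patient
#'   whose follow-up ends before 30 June but who has a January episode, so
#'   the period-prevalence numerator counts a patient the mid-year
#'   denominator does not.
#'
#' @param name One of the documented fixture names.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
make_worked_fixture <- function(name, dir) {
  name <- match.arg(name, FIXTURE_NAMES)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- switch(
    name,
    published_prevalence_pairs = {
      pairs <- reference_prevalence_pairs()
      ref <- data.frame(label = pairs$label, value = pairs$reference)
      cand <- data.frame(label = pairs$label, value = pairs$candidate)
      p <- file.path(dir, c("pairs.csv", "reference.csv", "candidate.csv"))
      utils::write.csv(as.data.frame(pairs), p[1], row.names = FALSE,
                       quote = FALSE, eol = "\n")
      utils::write.csv(ref, p[2], row.names = FALSE, quote = FALSE, eol = "\n")
      utils::write.csv(cand, p[3], row.names = FALSE, quote = FALSE, eol = "\n")
      p
    },
    washin_boundary = {
      patients <- tibble::tibble(
        patient_id = c("W89", "W90"),
        registration_date = as.Date("2010-01-01"),
        quality_start_date = as.Date(NA),
        transfer_out_date = as.Date(NA),
        death_date = as.Date(NA),
        last_collection_date = as.Date("2012-12-31"),
        sex = c("female", "male"),
        acceptable_quality = TRUE, duplicate_excluded = FALSE
      )
      events <- tibble::tibble(
        patient_id = c("W89", "W90"),
        # registration + 89 and + 90 days respectively
        event_date = as.Date(c("2010-03-31", "2010-04-01")),
        code = "X1", flag = NA_character_
      )
      write_fixture_bundle(dir, patients, events,
                           list(name = "washin_demo", chronicity = "lifelong",
                                codes = list("X1")))
    },
    period_asymmetry = {
      patients <- tibble::tibble(
        patient_id = c("A_exits_early", "B_full", "C_full"),
        registration_date = as.Date("2008-01-01"),
        quality_start_date = as.Date(NA),
        transfer_out_date = as.Date(c("2010-03-01", NA, NA)),
        death_date = as.Date(NA),
        last_collection_date = as.Date("2010-12-31"),
        sex = c("female", "male", "female"),
        acceptable_quality = TRUE, duplicate_excluded = FALSE
      )
      events <- tibble::tibble(
        patient_id = c("A_exits_early", "B_full"),
        event_date = as.Date(c("2010-01-10", "2010-07-05")),
        code = "ACU", flag = NA_character_
      )
      write_fixture_bundle(dir, patients, events,
                           list(name = "acute_demo", chronicity = "acute",
                                expected_duration_days = 28L,
                                codes = list("ACU")))
    }
  )
  invisible(paths)
}

write_fixture_bundle <- function(dir, patients, events, disease_cfg) {
  p <- file.path(dir, c("patients.csv", "events.csv", "disease.json"))
  write_registry(patients, events, p[1], p[2])
  jsonlite::write_json(disease_cfg, p[3], auto_unbox = TRUE, pretty = TRUE)
  p
}
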