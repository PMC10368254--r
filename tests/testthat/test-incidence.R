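lifelong_d <- disease_definition("demo", "lifelong", codes = "D1")
acute28_d <- disease_definition("acute28", "acute", 28, codes = "D1")

test_that("the 90-day wash-in boundary is inclusive of day 90", {
  p <- dplyr::bind_rows(make_patient("d89", "2010-01-01"),
                        make_patient("d90", "2010-01-01"))
  ev <- make_events(c("d89", "d90"), c("2010-03-31", "2010-04-01"))
  fu <- derive_follow_up(p)
  inc <- identify_incident_events(ev, lifelong_d, fu)
  expect_equal(inc$patient_id, "d90")
  expect_equal(inc$incident_date, as.Date("2010-04-01"))
})

test_that("recurrence lookback keeps only events clear of the previous record", {
  p <- make_patient("P1", "2009-01-01")
  base <- as.Date("2010-01-01")
  ev <- make_events("P1", base + c(0, 20, 60))
  inc <- identify_incident_events(ev, acute28_d, derive_follow_up(p))
  expect_equal(inc$incident_date, base + c(0, 60))
  # a record exactly one duration back still blocks incidence
  ev2 <- make_events("P1", base + c(0, 28))
  inc2 <- identify_incident_events(ev2, acute28_d, derive_follow_up(p))
  expect_equal(inc2$incident_date, base)
})

test_that("a lifelong first record inside the wash-in bars the patient forever", {
  p <- make_patient("P1", "2005-12-01")
  ev <- make_events(c("P1", "P1"), c("2006-01-01", "2009-01-01"))
  inc <- identify_incident_events(ev, lifelong_d, derive_follow_up(p))
  expect_equal(nrow(inc), 0)
})

test_that("incident events must fall inside follow-up", {
  p <- make_patient("P1", "2005-01-01", transfer = "2008-01-01")
  ev <- make_events("P1", "2009-01-01")  # after transfer out
  inc <- identify_incident_events(ev, lifelong_d, derive_follow_up(p))
  expect_equal(nrow(inc), 0)
})

test_that("person-time matches hand-derived day counts", {
  # full year, washed in before 1 January, no event
  p <- make_patient("full", "2005-01-01")
  fu <- derive_follow_up(p)
  no_ep <- build_exposure_episodes(make_events(character(), character()),
                                   lifelong_d, fu)
  expect_equal(person_time_by_year(2010, lifelong_d, fu, no_ep), 365L)
  expect_equal(person_time_by_year(2012, lifelong_d, fu, no_ep), 366L)  # leap

  # wash-in and onset bound the year from both sides: 2010-05-30..2010-08-14
  p2 <- make_patient("mid", "2010-03-01")
  fu2 <- derive_follow_up(p2)
  ep2 <- build_exposure_episodes(make_events("mid", "2010-08-15"),
                                 lifelong_d, fu2)
  expect_equal(person_time_by_year(2010, lifelong_d, fu2, ep2), 77L)

  # follow-up ended before the year opens
  p3 <- make_patient("gone", "2005-01-01", transfer = "2009-12-31")
  fu3 <- derive_follow_up(p3)
  expect_equal(person_time_by_year(2010, lifelong_d, fu3, no_ep), 0L)
})

test_that("patients with under 90 days' registration contribute no denominator", {
  p <- make_patient("short", "2010-06-01", transfer = "2010-08-01")
  fu <- derive_follow_up(p)
  no_ep <- build_exposure_episodes(make_events(character(), character()),
                                   lifelong_d, fu)
  expect_equal(person_time_by_year(2010, lifelong_d, fu, no_ep), 0L)
})

test_that("recurrent-disease person-time excludes exposure windows only", {
  p <- make_patient("P1", "2009-01-01")
  fu <- derive_follow_up(p)
  ev <- make_events(c("P1", "P1"), c("2010-03-01", "2010-07-01"))
  ep <- build_exposure_episodes(ev, acute28_d, fu)
  got <- person_time_by_year(2010, acute28_d, fu, ep)
  expect_equal(got, 365L - 56L)  # two disjoint 28-day episodes
  oracle <- enumerate_person_days(2010, acute28_d, fu, events_by_id(ev, acute28_d))
  expect_equal(got, oracle)
})

test_that("annual person-time equals the day-enumeration oracle on random registries", {
  rr <- random_registry(60, years = 2008:2012, seed = 101)
  fu <- derive_follow_up(rr$patients)
  for (d in list(lifelong_d, acute28_d)) {
    ep <- build_exposure_episodes(rr$events, d, fu)
    ev_ids <- events_by_id(rr$events, d)
    for (y in 2008:2012) {
      expect_equal(person_time_by_year(y, d, fu, ep),
                   enumerate_person_days(y, d, fu, ev_ids),
                   info = sprintf("%s year %d", d$name, y))
    }
  }
})

test_that("per-patient yearly person-time conserves the patient's total at-risk span", {
  rr <- random_registry(40, years = 2008:2012, seed = 202)
  fu <- derive_follow_up(rr$patients)$followup
  ep <- build_exposure_episodes(rr$events, lifelong_d, fu)
  per_year <- lapply(2008:2012, function(y) {
    person_time_by_year(y, lifelong_d, fu, ep, by_patient = TRUE)
  })
  total <- dplyr::bind_rows(per_year) |>
    dplyr::summarise(days = sum(person_days), .by = patient_id)
  onset <- setNames(as.integer(ep$onset), ep$patient_id)
  for (i in seq_len(nrow(fu))) {
    id <- fu$patient_id[i]
    a <- max(as.integer(as.Date("2008-01-01")), as.integer(fu$fu_start[i]),
             as.integer(fu$registration_date[i]) + 90L)
    b <- min(as.integer(as.Date("2013-01-01")), as.integer(fu$fu_end[i]) + 1L,
             if (!is.na(onset[id])) onset[id] else .Machine$integer.max)
    eligible <- as.integer(fu$fu_end[i]) -
      as.integer(fu$registration_date[i]) >= 90L
    want <- if (eligible) max(0L, b - a) else 0L
    got <- total$days[total$patient_id == id]
    expect_equal(if (length(got)) got else 0L, want, info = id)
  }
})

test_that("incidence monotonicity and scale linearity hold", {
  rr <- random_registry(80, years = 2008:2012, seed = 303)
  fu <- derive_follow_up(rr$patients)
  n_inc <- function(washin) {
    nrow(identify_incident_events(rr$events, acute28_d, fu,
                                  washin_days = washin))
  }
  counts <- vapply(c(0L, 30L, 90L, 180L, 365L), n_inc, 1L)
  expect_true(all(diff(counts) <= 0))  # longer wash-in never adds cases

  w <- observation_window("2008-01-01", "2012-12-31")
  r5 <- annual_incidence(rr$patients, rr$events, acute28_d, w, scale = 1e5)
  r6 <- annual_incidence(rr$patients, rr$events, acute28_d, w, scale = 1e6)
  expect_equal(r6$rate, r5$rate * 10)
})

test_that("a year with no person-time reports a missing rate, not an error", {
  p <- make_patient("P1", "2010-01-01", transfer = "2010-02-01")
  inc <- annual_incidence(p, make_events(character(), character()),
                          lifelong_d, observation_window("2010-01-01",
                                                         "2011-12-31"))
  expect_true(all(is.na(inc$rate)))
  expect_true(all(inc$numerator == 0))
})

test_that("chronicity constrains incident-event multiplicity per patient", {
  rr <- random_registry(80, years = 2008:2012, seed = 404)
  fu <- derive_follow_up(rr$patients)
  inc_l <- identify_incident_events(rr$events, lifelong_d, fu)
  expect_true(all(table(inc_l$patient_id) <= 1))
  inc_a <- identify_incident_events(rr$events, acute28_d, fu)
  gaps <- inc_a |>
    dplyr::arrange(patient_id, incident_date) |>
    dplyr::mutate(gap = as.integer(incident_date - dplyr::lag(incident_date)),
                  .by = patient_id)
  expect_true(all(gaps$gap >= 28, na.rm = TRUE))
})
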