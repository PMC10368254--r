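lifelong_d <- disease_definition("demo", "lifelong", codes = "D1")
acute28_d <- disease_definition("acute28", "acute", 28, codes = "D1")

test_that("point prevalence counts mid-year overlap of follow-up and exposure", {
  p <- dplyr::bind_rows(
    make_patient("case", "2005-01-01", last = "2012-12-31"),
    make_patient("ctrl", "2005-01-01", last = "2012-12-31"))
  fu <- derive_follow_up(p)
  ep <- build_exposure_episodes(make_events("case", "2010-05-01"),
                                lifelong_d, fu)
  est <- point_prevalence(2009:2012, ep, fu, lifelong_d, scale = 100)
  expect_equal(est$numerator, c(0L, 1L, 1L, 1L))  # counted from 2010 onward
  expect_equal(est$population, rep(2L, 4))
  expect_equal(est$rate, c(0, 50, 50, 50))
})

test_that("an episode missing 30 June does not count toward point prevalence", {
  p <- make_patient("P1", "2005-01-01")
  fu <- derive_follow_up(p)
  ep <- build_exposure_episodes(make_events("P1", "2010-08-01"),
                                disease_definition("nl", "non_lifelong", 61,
                                                   codes = "D1"), fu)
  est <- point_prevalence(2010, ep, fu, lifelong_d, scale = 100)
  expect_equal(est$numerator, 0L)
})

test_that("a five-patient fixture reproduces its hand-enumerated rate", {
  # 4 of 5 followed on 2010-06-30; 2 of those exposed -> 2/4
  p <- dplyr::bind_rows(
    make_patient("e1", "2005-01-01"),
    make_patient("e2", "2005-01-01"),
    make_patient("u1", "2005-01-01"),
    make_patient("u2", "2005-01-01"),
    make_patient("out", "2005-01-01", transfer = "2010-01-01"))
  fu <- derive_follow_up(p)
  ep <- build_exposure_episodes(
    make_events(c("e1", "e2"), c("2009-01-01", "2010-06-30")), lifelong_d, fu)
  est <- point_prevalence(2010, ep, fu, lifelong_d, scale = 100)
  expect_equal(est$numerator, 2L)
  expect_equal(est$population, 4L)
  expect_equal(est$rate, 50)
})

test_that("period prevalence spans year boundaries and counts patients once", {
  p <- make_patient("P1", "2005-01-01")
  fu <- derive_follow_up(p)
  # episode 2010-12-20..2011-01-16 overlaps both years
  ep <- build_exposure_episodes(make_events("P1", "2010-12-20"), acute28_d, fu)
  est <- period_prevalence(2010:2011, ep, fu, acute28_d, scale = 100)$estimates
  expect_equal(est$numerator, c(1L, 1L))
  # three episodes in one year still count the patient once
  ep3 <- build_exposure_episodes(
    make_events(rep("P1", 3), c("2010-01-01", "2010-04-01", "2010-09-01")),
    acute28_d, fu)
  est3 <- period_prevalence(2010, ep3, fu, acute28_d, scale = 100)$estimates
  expect_equal(est3$numerator, 1L)
})

test_that("the literal mid-year denominator can exclude a numerator patient, and is flagged", {
  dir <- withr::local_tempdir()
  make_worked_fixture("period_asymmetry", dir)
  reg <- load_registry(file.path(dir, "patients.csv"),
                       file.path(dir, "events.csv"))
  d <- load_disease_definition(file.path(dir, "disease.json"))
  fu <- derive_follow_up(reg$patients)
  ep <- build_exposure_episodes(reg$events, d, fu)
  res <- period_prevalence(2010, ep, fu, d, scale = 100)
  # the early-exit patient is in the numerator by the overlap rule but not
  # in the mid-year denominator
  expect_equal(res$estimates$numerator, 2L)
  expect_equal(res$estimates$population, 2L)
  expect_equal(res$consistency$patient_id, "A_exits_early")
  expect_equal(res$consistency$year, 2010)
})

test_that("acute episodes covering 30 June give equal point and period numerators", {
  rr <- random_registry(50, years = 2009:2011, seed = 505)
  fu <- derive_follow_up(rr$patients)$followup
  # restrict to the mid-year population so numerator scopes coincide
  fu <- fu[fu$fu_start <= midyear(2010) & fu$fu_end >= midyear(2010), ]
  # force all episodes to straddle the midpoint
  ev <- make_events(unique(rr$events$patient_id), "2010-06-20")
  long_acute <- disease_definition("straddle", "acute", 30, codes = "D1")
  ep <- build_exposure_episodes(ev, long_acute, fu)
  ep <- ep[ep$onset <= midyear(2010) & ep$end >= midyear(2010), ]
  point <- point_prevalence(2010, ep, fu, long_acute, scale = 100)
  period <- period_prevalence(2010, ep, fu, long_acute, scale = 100)$estimates
  expect_equal(point$numerator, period$numerator)
  expect_equal(point$population, period$population)
})

test_that("point prevalence of a lifelong disease is non-decreasing in a closed population", {
  set.seed(606)
  n <- 60
  p <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_patient(sprintf("C%02d", i), "2000-01-01", last = "2020-12-31")
  }))
  onset_idx <- sample.int(n, 35)
  ev <- make_events(sprintf("C%02d", onset_idx),
                    as.Date("2004-01-01") + sample.int(5000, 35, replace = TRUE))
  fu <- derive_follow_up(p)
  ep <- build_exposure_episodes(ev, lifelong_d, fu)
  est <- point_prevalence(2004:2020, ep, fu, lifelong_d, scale = 100)
  expect_true(all(diff(est$numerator) >= 0))
  expect_true(all(est$rate / est$scale >= 0 & est$rate / est$scale <= 1))
})

test_that("simulated point prevalence recovers the Monte-Carlo truth", {
  cfg <- simulation_config(n_patients = 20000, onset_hazard = 0.01,
                           exit_hazard = 0.03, death_hazard = 0.01,
                           seed = 2024)
  sim <- simulate_registry(cfg)
  d <- simulated_disease(cfg)
  fu <- derive_follow_up(sim$patients)
  ep <- build_exposure_episodes(sim$events, d, fu)
  years <- c(2008, 2014, 2019)
  est <- point_prevalence(years, ep, fu, d, scale = 1)
  truth <- prevalence_truth_mc(cfg, years, n_rep = 150000)
  expect_true(all(truth$se > 0))
  for (i in seq_along(years)) {
    p_hat <- est$rate[i]
    se <- sqrt(truth$se[i]^2 +
                 p_hat * (1 - p_hat) / est$population[i])
    expect_lt(abs(p_hat - truth$prevalence[i]), 3 * se)
  }
})
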