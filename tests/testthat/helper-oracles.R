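# Independent oracles and in-code fixtures shared across the suite.
# These deliberately re-derive results by the most literal route available
# (day-by-day enumeration, direct moment formulas) so they cannot share a
# defect with the vectorised implementation they check.

# Brute-force Lin's CCC straight from the moment definition, one term at a
# time, population (1/n) moments.
brute_force_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Asymptotic z-transform CI for the CCC, written out from Lin's variance
# formula (1989, with the 2000 erratum) without reusing package internals.
brute_force_ccc_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  p <- brute_force_ccc(x, y)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  r <- mean((x - mx) * (y - my)) / sqrt(sx2 * sy2)
  u <- (my - mx) / (sx2 * sy2)^(1 / 4)
  v <- ((1 - r^2) * p^2 * (1 - p^2) / r^2 +
          2 * p^3 * (1 - p) * u^2 / r -
          p^4 * u^4 / (2 * r^2)) / (n - 2)
  z <- atanh(p)
  half <- qnorm(1 - (1 - level) / 2) * sqrt(v) / (1 - p^2)
  c(lower = tanh(z - half), upper = tanh(z + half))
}

# Day-by-day person-time enumeration: walks every calendar day of `year`
# and applies the at-risk rules literally, one day at a time.
enumerate_person_days <- function(year, definition, followup, event_dates_by_id,
                                  washin_days = 90L) {
  fu <- followup
  if (is.list(fu) && !is.data.frame(fu)) fu <- fu$followup
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  total <- 0L
  for (i in seq_len(nrow(fu))) {
    if (as.integer(fu$fu_end[i]) - as.integer(fu$registration_date[i]) <
        washin_days) next
    ev <- event_dates_by_id[[fu$patient_id[i]]]
    at_risk <- days >= fu$fu_start[i] &
      days >= fu$registration_date[i] + washin_days &
      days <= fu$fu_end[i]
    if (!is.null(ev) && length(ev) > 0) {
      if (definition$chronicity == "lifelong") {
        at_risk <- at_risk & days < min(ev)
      } else {
        dur <- definition$expected_duration_days
        exposed <- rep(FALSE, length(days))
        for (t in as.list(ev)) {
          exposed <- exposed | (days >= t & days <= t + dur - 1L)
        }
        at_risk <- at_risk & !exposed
      }
    }
    total <- total + sum(at_risk)
  }
  total
}

# A small hand-enumerable registry: helpers to build one-row patients.
make_patient <- function(id, reg, last = "2020-12-31", quality = NA,
                         transfer = NA, death = NA, sex = "female",
                         acceptable = TRUE, duplicate = FALSE) {
  tibble::tibble(
    patient_id = id,
    registration_date = as.Date(reg),
    quality_start_date = as.Date(quality),
    transfer_out_date = as.Date(transfer),
    death_date = as.Date(death),
    last_collection_date = as.Date(last),
    sex = sex, acceptable_quality = acceptable,
    duplicate_excluded = duplicate
  )
}

make_events <- function(ids, dates, codes = "D1") {
  tibble::tibble(patient_id = ids, event_date = as.Date(dates),
                 code = codes, flag = NA_character_)
}

# Random registry + event stream for property tests, built directly rather
# than through simulate_registry so registry-code defects cannot cancel out.
random_registry <- function(n, years = 2006:2015, seed) {
  set.seed(seed)
  day0 <- as.Date(sprintf("%d-01-01", min(years) - 2))
  span <- as.integer(as.Date(sprintf("%d-12-31", max(years))) - day0)
  reg <- day0 + sample.int(span, n, replace = TRUE)
  fu_len <- sample.int(3000L, n, replace = TRUE)
  patients <- tibble::tibble(
    patient_id = sprintf("R%04d", seq_len(n)),
    registration_date = reg,
    quality_start_date = as.Date(NA),
    transfer_out_date = as.Date(ifelse(runif(n) < 0.3,
                                       as.integer(reg) + fu_len, NA)),
    death_date = as.Date(NA),
    last_collection_date = as.Date(sprintf("%d-12-31", max(years))),
    sex = "female", acceptable_quality = TRUE, duplicate_excluded = FALSE
  )
  n_ev <- rpois(n, 1.2)
  events <- make_events(
    rep(patients$patient_id, n_ev),
    day0 + sample.int(span + 400L, sum(n_ev), replace = TRUE))
  list(patients = patients, events = events)
}

events_by_id <- function(events, definition) {
  ev <- events[events$code %in% definition$codes, ]
  split(ev$event_date, ev$patient_id)
}
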