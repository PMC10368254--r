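---
title: "Methods: incidence, prevalence and concordance from patient registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incidence, prevalence and concordance from patient registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiregister)
```

# The estimation problem

Routine primary-care records give, per patient, an administrative history
(registration, possibly a data-quality start date, possibly transfer-out or
death, and the practice's last data-collection date) and a stream of dated
clinical codes. Turning these into annual incidence and prevalence series
is mostly careful bookkeeping, and the bookkeeping is where studies
disagree: when does follow-up start and end, when is a record "new
disease" rather than a repeat mention of an old one, and who belongs in
the denominator. This package fixes one coherent set of rules — the
conventions of UK primary-care database epidemiology — and implements them
end to end so the same inputs always give the same series.

## Follow-up and eligibility

Follow-up runs from the registration date (or, when `uts_applies = TRUE`,
the later of registration and the patient's data-quality start date — the
"up-to-standard" rule used by sources that audit practice data quality) to
the earliest of transfer-out, death, and the practice's final
data-collection date. A patient is retained only with at least one day of
follow-up, acceptable research quality and no duplicate flag; everyone
else lands in an exclusions report with a named reason. Duplicate
detection itself is out of scope: `duplicate_excluded` is an input flag,
because cross-source practice-migration deduplication needs source
internals a generic registry does not carry.

## Chronicity and exposure episodes

A disease definition is a code list plus a chronicity class:

* **lifelong** — once presented, the patient is exposed until follow-up
  ends; exactly one episode per patient.
* **non_lifelong / acute** — each record opens an episode of
  `expected_duration_days` (units: days; no default — this is a clinical
  judgement the user must make). Overlapping *or abutting* episodes merge:
  a repeat record inside or immediately after the expected duration is
  read as the same illness continuing, not a new one.

Episodes are clipped at follow-up end — a patient cannot be *observed*
prevalent after observation stops — but deliberately not at follow-up
start: a code recorded before follow-up begins still establishes the
presentation date, so the patient is prevalent from registration onward.
Such a record can never be *incident*, since incidence requires the record
to fall inside follow-up. Same-day duplicate records collapse to one,
which makes episode construction order-independent and idempotent (the
test suite permutes event order to check this).

## Incidence

An event at time *t* is incident when all of:

1. *t* lies inside follow-up;
2. *t* is at least 90 days after registration ("90 days or more" — day 90
   itself counts). This wash-in exists because a fresh registration often
   triggers the recording of pre-existing conditions; treating those as
   new cases would inflate incidence.
3. the event is novel: for lifelong diseases, the first-ever matching
   record; otherwise, no matching record in the lookback window
   `[t - expected_duration_days, t)`.

The wash-in is a tunable (`washin_days`, default 90 days) and bounds the
denominator as well: a patient contributes no at-risk time during their
wash-in, and patients with under 90 days between registration and
follow-up end contribute nothing at all. The per-year at-risk interval is

> from the latest of 1 January, follow-up start, and registration + 90 days
> to the earliest of 31 December and follow-up end,

censored at disease onset. For lifelong diseases "onset" is the
presentation date. For recurrent diseases the formula's single "onset" is
ambiguous; the package's reading is that exposure windows are not at-risk
time: each episode's days are subtracted and the patient re-enters the
risk set when the episode ends. This keeps the numerator (which can recur)
and the denominator consistent for repeatable events; it is a documented
interpretation, not the only possible one.

Person-days convert to person-years at 365.25 days/year — a convention
chosen once and used everywhere, so leap years need no special casing.
Rates are reported per `scale` person-years. With `scale = "auto"` the
package picks the smallest power of ten in 10^2..10^6 that lifts the
period-average rate to at least 1, which mirrors the common editorial
practice of matching the denominator to the magnitude of the numerator
while staying deterministic.

## Prevalence

* **Point prevalence** (chronic and non-lifelong diseases): numerator =
  patients whose follow-up *and* some exposure episode cover 30 June of
  the year; denominator = all retained patients whose follow-up covers
  30 June. The midpoint is always 30 June, never 1 July.
* **Period prevalence** (acute diseases): numerator = patients whose
  follow-up and some episode each overlap any part of the year (one count
  per patient per year); denominator = again the mid-year population.

The period-prevalence denominator is asymmetric with its numerator: a
patient who leaves in March with a January episode is in the numerator but
not the mid-year denominator. The package implements the definition as
stated and surfaces every such patient in a consistency report rather than
silently symmetrising, because "fixing" it would change the estimand.
The mapping from chronicity to prevalence type is a default
(`type = "auto"`: period for acute, point otherwise), not a constraint —
some published studies use period prevalence for chronic conditions, so
the type can be forced.

No wash-in applies to prevalence: wash-in exists to protect *incidence*
from old disease recorded late, and an old record is perfectly good
evidence of *prevalent* disease.

## Lin's concordance correlation coefficient

To validate a series against external estimates the package uses Lin's
CCC,

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

with population (1/n) moments by default, matching Lin (1989) and the
widely used reference implementations; a sample-moment variant sits behind
`moments = "sample"` because both conventions circulate. Pairing is an
inner join on labels with missing-value pairs dropped and reported; fewer
than two surviving pairs is an error, and two series that are both
constant with equal means give 0/0 and are reported as an error rather
than 1.

The confidence interval is the Fisher z-transform interval with Lin's
asymptotic variance (including the published erratum's correction). That
specific CI construction is this package's documented choice among several
in circulation. A CCC of exactly ±1 yields the degenerate interval
[ccc, ccc]. Interpretation bands are half-open as commonly recommended:
<0.90 poor, [0.90, 0.95) moderate, [0.95, 0.99) substantial, ≥0.99 almost
perfect — so 0.95 is "substantial" and 0.99 is "almost perfect".

The bundled `reference_prevalence_pairs()` comparison is computed with
each pair on its study's own printed denominator scale. Pooling values
printed per 100, per 10,000 and per 1,000,000 into one coefficient weights
conditions very unevenly; the package keeps the printed-scale convention
for this dataset because that is how such cross-study comparisons are
reported, and `concordance()` accepts any rescaled series when a
common-scale analysis is wanted.

## The synthetic registry

`simulate_registry()` exists so every estimator is testable with known
truth and no real data. It emulates: staggered registration (uniform entry
over a span that starts, by default, ten years before the observation
window so the window opens with an established population); exit and death
as independent constant hazards (defaults 0.05 and 0.01 per person-year,
realistic orders for UK practice turnover and adult mortality); first
disease onset as a constant hazard from registration; events recorded only
while the record is live; and, for acute diseases, recurrence drawn after
the current episode ends, so simulated inter-event gaps exceed the
expected duration by construction. Competing risks resolve by the minimum
of the exponentials.

It does **not** emulate: age structure or age-dependent hazards, secular
trends in recording, practice-level clustering, code-dictionary noise, or
onset before registration. Passing recovery tests therefore shows the
estimators are consistent under the stated rules — not that those rules
capture every bias of real registry data (recording drift and
incentive-driven coding changes being the obvious ones).

Ground truth for prevalence comes from an independent large Monte-Carlo
replicate whose exposure status is read directly off the simulated latent
histories, not through the estimator code, and is always reported with a
standard error.

# Numerical and degenerate-input choices

* All interval arithmetic is closed-start/half-open-end on integer day
  counts; human-facing dates print the last included day. This removes
  every ±1-day ambiguity: 31 December belongs to its year (internal end
  1 January of the next), an episode of duration *d* starting at *t* covers
  days *t* … *t*+*d*−1, and the lookback `[t − d, t)` excludes *t* itself.
* Dates are strict ISO-8601; an impossible date is a row-level diagnostic
  (with row and field), never a silent `NA` or a locale guess.
* Events before 1900 or after the registry's latest collection date are
  flagged but kept — visibility over silent loss.
* A year with zero person-time (or an empty mid-year population) reports a
  missing rate, never a division error; an empty cohort produces valid
  all-zero outputs.
* Absent optional dates behave as "no constraint": follow-up end is the
  minimum over the dates that exist.

# Test design and problem sizes

Property tests run on registries of 40–220 random patients over 5–10
calendar years, where the day-by-day enumeration oracle (which literally
walks every calendar day and applies the rules one day at a time) is exact
and fast. Estimator recovery uses 50,000 simulated patients for incidence
(hazard 0.005/person-year, judged against three Monte-Carlo standard
errors) and 20,000 analysis plus 150,000 truth-replicate patients for
prevalence. These sizes give Monte-Carlo error well below the effects
being checked while keeping the whole suite around ten seconds.

# Known limitations

Exact-string code matching only; no cross-dictionary mapping. No age/sex
standardisation (two common comparator conventions, direct standardisation
to an index year and age-restricted denominators, are out of scope). The
recurrent-disease denominator treatment is an interpretation (documented
above). CCC is known to be unstable for heavy-tailed or near-constant
series; the interpretation bands do not rescue that, and users comparing
long stable series should inspect the pairs, not just the coefficient.
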