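---
title: "Methods: clean-window cohorts, stratified rates and cross-database pooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clean-window cohorts, stratified rates and cross-database pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgrates)
```

## The estimand

For each adverse event of special interest (AESI), database, age group and
sex, the target is the background incidence rate per 100 000 person-years in
an unvaccinated reference period: events during time at risk divided by
person-time at risk. Across databases the targets are a pooled typical rate,
the between-database variance of log rates, and the range of rates a *new*
database would plausibly show (the prediction interval), finally summarised
as a CIOMS frequency class.

## Cohort model

All intervals in the package are closed calendar-date intervals.

* **Index dates.** 1 January of each index year (default 2017–2019). The
  time-at-risk window is the index year itself, 1 January to 31 December;
  since these years are non-leap, this equals index + 364 days.
* **Eligibility.** A person enters at an index date when one normalised
  observation period both contains the index date and starts at least 365
  days before it (`start <= index - 365`), i.e. a full prior year of
  continuous observation. Periods are normalised first: sorted per person,
  with overlapping *or abutting* (zero-day gap) periods merged, so
  fragmented enrolment records cannot manufacture eligibility gaps.
* **Qualification.** A condition record qualifies for an outcome if the
  outcome imposes no setting rule, or the record is inpatient (and, for
  Guillain-Barré syndrome, in the primary diagnosis position).
* **Clean-window exclusion.** A qualifying event in
  `[index - clean_window, index - 1]` keeps the person out of that outcome's
  cohort for that year. An event **on** the index date is *not* an
  exclusion — the exclusion window is defined strictly before the index —
  but counts as an event on day 1 of follow-up. This was a genuinely open
  reading; the strict-before convention keeps the exclusion window and the
  at-risk window disjoint.
* **Follow-up walk.** From the index date, time is at risk until the first
  qualifying event; the event day itself is counted as at-risk time (the
  person was at risk up to and including that day) and the event is counted.
  Risk is then suspended for `clean_window` days and resumes after it,
  repeating until the censor date `min(index + 364, end of the observation
  period containing the index, death)`. Records falling inside a suspended
  window are ignored — they are repeat codes of the same episode by
  definition of the clean window.
* **Person-time policy.** Whether suspended clean-window days count as
  person-time is not decidable from the design narrative alone; the package
  defaults to *excluding* them (risk resumes "after the clean window") and
  exposes `count_clean_window_time = TRUE` for the alternative reading.
  Event counts are identical under both policies; only the denominator
  changes.
* **No re-entry within a year.** If the observation period containing the
  index ends mid-year, a later period in the same year does not resume
  follow-up; a single censoring event per year keeps person-time
  interpretable.
* **Strata.** Age is index year minus birth year, in eight groups (1–5,
  6–17, 18–34, 35–54, 55–64, 65–74, 75–84, 85+). Age 0 (and, defensively,
  records implying birth after the index year) and sexes outside
  male/female are excluded and tallied in the run manifest, never silently
  dropped. Year-by-year, the same person can move between age strata.

The engine is interval algebra (it only iterates over events, not days). Its
correctness contract is exact equality — event counts and at-risk day totals
— with a brute-force day-by-day simulator that applies the same rules
literally; the test suite enforces this on randomly generated databases of
1000 persons across all fifteen outcome definitions and three index years,
a size chosen to exercise every rule combination while keeping the
brute-force pass fast.

## Incidence estimation

Person-days are converted at 365.25 days per person-year (the conventional
epidemiological divisor; configurable). The three index years are pooled
into one estimate per database stratum by default (`by_year = TRUE` gives
per-year cells). The 95% CI is the exact Poisson (Garwood) interval,
`qgamma(0.025, x)/PY` to `qgamma(0.975, x + 1)/PY`, chosen because AESI
counts in small strata are routinely in single digits where normal
approximations fail; with zero events the lower limit is 0. The
minimum-cell-count rule defaults to *report when events ≥ 5*; the literal
"exceeds 5" reading (report only > 5) is available via `strict_greater`.
Suppressed cells keep their person-years internally (so pooling can log the
exclusion) but are masked in public tables.

## Random-effects pooling

Pooling operates on the natural-log rate scale with the delta-method
Poisson standard error, `y = ln(events/PY)`, `se = 1/sqrt(events)` — the
standard choice for rate meta-analysis; the original analysis names only
the estimator, so scale and variance formula are documented package
decisions. Zero-event cells have no finite log rate and are excluded by
default (logged per stratum as `n_zero_excluded`); an optional 0.5-event
continuity correction retains them. Suppressed cells never enter pooling,
keeping the pooled estimate consistent with what a public table could show.

The DerSimonian–Laird estimator is implemented from its moment equations
(`Q`, `C = sum(w) - sum(w^2)/sum(w)`, `tau2 = max(0, (Q - (k-1))/C)`), with
random-effects weights `1/(v_i + tau2)`, a normal-quantile CI, and
back-transformation by exponentiation (asymmetric on the rate scale).
Pooling requires k ≥ 2 and refuses otherwise (a classed condition; the
grouped wrapper reports such strata with `NA` results rather than dropping
the row). The prediction interval is the Higgins-type t-interval with k − 2
degrees of freedom, matching the convention of the standard R
meta-analysis tooling; it is undefined (NA, not an error) for k < 3.
τ̂² = 0 exactly when Q ≤ k − 1; I² is reported as max(0, (Q − (k−1))/Q).

The implementation is cross-checked in tests against `metafor::rma(method =
"DL")` and against a frozen independently hand-computed three-study closed
form (tolerance 1e−10 internally, 1e−6 on the back-transformed interval).

## CIOMS classification

Thresholds act on the per-person-year fraction with inclusive lower
boundaries: ≥ 0.1 very common, ≥ 0.01 common, ≥ 0.001 uncommon, ≥ 0.0001
rare, below very rare. Exactly 1/100 (1000 per 100 000 PY) is therefore
common. The classifier is a monotone step function returning an ordered
factor.

## What the synthetic generator emulates — and what it does not

`generate_population()` / `generate_events()` / `generate_network()` draw:

* persons with configurable birth-year range (default 1930–2015) and female
  fraction (default 0.51, matching the mild female excess typical of these
  sources);
* one observation period per person, starting uniformly in a configurable
  window (default 2014–2015 so most persons are eligible by 2017),
  ending by an exponential dropout clock (default hazard 0.05/year),
  administrative end of data capture (default 2019-12-31), or death
  (default hazard 0.01/year); deaths truncate the period at the death date
  and are recorded only when observed;
* events as a homogeneous Poisson process within person × calendar-year
  cells, with mean = true stratum rate × observed person-time. The true
  rate is `baseline × age multiplier × sex multiplier × exp(u_d)` with
  `u_d ~ N(0, db_sigma^2)` per database and outcome. The default
  `db_sigma = 0.3` produces the several-fold between-database spread seen
  in real networks. Default baselines and age patterns follow the broad
  epidemiology of each AESI (cardiovascular events rising steeply with age,
  anaphylaxis and appendicitis skewed young, Guillain-Barré and transverse
  myelitis very rare throughout); they are chosen once for testability and
  plausibility, not as estimates of any real population.
* care setting and diagnosis position as independent Bernoulli draws;
  primary-care-like databases drop events drawn as inpatient (the source
  never captures them), and the pipeline additionally refuses to use such
  databases for inpatient-required outcomes.

Events are generated over *all* observed time, including before index dates
and inside clean windows, so the exclusion logic is genuinely exercised
rather than vacuously true. The homogeneous-within-cell Poisson form makes
the estimand analytic, which is what lets tests assert recovery.

Deliberately **not** emulated: diagnostic coding vocabularies and phenotype
validity, seasonality, within-person comorbidity correlation, and
observation windows linked to birth (raw tables may show observation before
birth; the engine excludes such person-years and tallies them). Passing
tests therefore demonstrate the correctness of the algebra and estimators
under the stated generative model — not the epidemiological accuracy of any
real database, where measurement error and phenotype misclassification
dominate.

**Seeding.** One master seed; per-database substreams are derived by fixed
arithmetic on (seed, database index) and per-outcome substreams on
(database seed, outcome index), so appending a database or outcome leaves
earlier draws unchanged, and identical configurations are byte-identical on
disk.

## Numerical and degenerate-input choices

* Dates are integer days internally; no floating-point date arithmetic.
* `n_persons = 0` yields empty, correctly-typed tables; downstream stages
  report zero eligibility rather than erroring.
* A censor date before the index (possible only in inconsistent input)
  contributes zero at-risk time rather than a negative segment.
* Invalid rows fail fast with classed conditions naming the offending rule
  (`bgrates_input_error`, `bgrates_config_error`, `bgrates_domain_error`,
  `bgrates_contract_error`, `bgrates_pooling_refused`).
* Rate/CI identities are exact to machine precision; test tolerances are
  1e−10 for closed forms and Monte-Carlo bands (3 standard errors; 90–98%
  coverage windows) for simulation-based checks.

## Problem sizes used by the test suite

The suite validates the oracle equivalence at 1000 persons × 15 outcomes ×
3 years; rate recovery on a single stratum simulated at a true 500 per
100 000 PY over ≥ 200 000 person-years; CI coverage over 500 Poisson
replicates at 2500 PY; heterogeneity recovery over 200 replicates of a
10-database network at 500 000 PY per database (with the prediction
interval checked against an 11th database); and a 20-database patient-level
network for the spread of log empirical rates against `db_sigma`. These
sizes were chosen to keep Monte-Carlo error comfortably inside the asserted
bands.

## Known limitations

* The recurrent-event model treats every post-clean-window event as a new
  episode; no severity, mortality attribution, or episode linkage.
* Only the DerSimonian–Laird τ² estimator is provided (no REML or
  Paule–Mandel), and no meta-regression or small-study-bias diagnostics —
  matching the scope of the original analysis.
* No age- or sex-standardised summary rates: strata are reported, never
  collapsed over demographics.
* The CIOMS ladder classifies the pooled point estimate; classification by
  prediction-interval overlap would need an explicit decision rule and is
  left to the analyst, who has `pi_low`/`pi_high` in the output.
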