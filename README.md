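# bgrates

Background (expected) incidence rates of adverse events of special interest
(AESIs) are the yardstick against which safety signals after vaccination are
judged: an observed post-vaccination rate only means something relative to
the rate the same population would have shown anyway. `bgrates` implements a
complete, tested pipeline for characterising such background rates across a
network of observational health databases, together with a synthetic
patient-level data generator with known ground truth so every stage can be
validated without access to any proprietary source.

It is aimed at pharmacoepidemiologists and safety-surveillance statisticians
who want the cohort algebra, the rate estimation and the cross-database
pooling of a network study as composable, pipe-friendly R functions.

## What it computes

**Cohort construction.** At each index date (1 January of 2017–2019) a
person enters an outcome's cohort if they were observed for the previous
365 days and had no qualifying event of that outcome during the outcome's
*clean window* (365 days for most AESIs, 30 for anaphylaxis, 183 for Bell's
palsy and encephalomyelitis) before the index date. Time at risk runs to the
earliest of day 365, end of observation and death. Events during follow-up
are counted (a person may contribute several); each counted event suspends
at-risk time for one clean window, and repeat records inside a clean window
are not counted. Some outcomes qualify only via inpatient records (both
strokes, acute myocardial infarction, encephalomyelitis), Guillain-Barré
syndrome only via inpatient records in the primary diagnosis position.

**Stratified incidence.** For each database × outcome × age group × sex
cell (eight age groups, 1–5 up to 85+, age = index year − birth year):

```
IR = events / person-years × 100 000
```

with the exact Poisson (Garwood) 95% CI, and cells under the minimum cell
count (default 5 events) suppressed from public output.

**Random-effects pooling.** Log rates y_i = ln(events_i / PY_i) with
se_i = 1/√events_i are pooled across databases with the DerSimonian–Laird
estimator (Q, τ², I²), a 95% CI, and a Higgins-type 95% prediction interval
t(0.975; k−2) · √(τ² + SE²) describing the rate expected in a *new*
database. Pooled rates are classified on the CIOMS frequency ladder
(very common ≥ 1/10, common ≥ 1/100, uncommon ≥ 1/1000, rare ≥ 1/10 000,
very rare below).

**Synthetic networks.** `generate_network()` draws multi-database
populations in which the true stratum rate is
baseline × age multiplier × sex multiplier × exp(u_d), with
u_d ~ N(0, σ²_db) drawn once per database — so heterogeneity, suppression
and pooling behaviour can be tested against known truth. Primary-care-like
databases capture no inpatient records and are skipped for
inpatient-required outcomes.

## Worked example

```r
library(bgrates)
library(dplyr)

cfg <- network_config(list(
  list(database_id = "claims_a", n_persons = 20000),
  list(database_id = "claims_b", n_persons = 20000),
  list(database_id = "ehr_c",    n_persons = 20000),
  list(database_id = "gp_d",     n_persons = 20000, primary_care = TRUE)
), seed = 2026)

res <- run_pipeline(run_config(cfg, seed = 2026, out_dir = tempfile()))

res$rates |>
  filter(outcome_id == "deep_vein_thrombosis", age_group == "65-74",
         sex == "female") |>
  select(database_id, events, person_years, rate, ci_low, ci_high, suppressed)
#> # A tibble: 4 × 7
#>   database_id events person_years  rate ci_low ci_high suppressed
#>   <chr>        <int>        <dbl> <dbl>  <dbl>   <dbl> <lgl>
#> 1 claims_a        12        2959.  406.   210.    708. FALSE
#> 2 claims_b         9        3017.  298.   136.    566. FALSE
#> 3 ehr_c           14        2717.  515.   282.    865. FALSE
#> 4 gp_d            12        2896.  414.   214.    724. FALSE

res$pooled |>
  filter(outcome_id == "deep_vein_thrombosis", sex == "female",
         !is.na(pooled_rate)) |>
  select(age_group, k, pooled_rate, pi_low, pi_high, tau2, cioms_category)
#> # A tibble: 6 × 7
#>   age_group     k pooled_rate pi_low pi_high   tau2 cioms_category
#>   <fct>     <int>       <dbl>  <dbl>   <dbl>  <dbl> <ord>
#> 1 18-34         3        139.   8.09   2375. 0      uncommon
#> 2 35-54         4        240.  59.8     961. 0.0680 uncommon
#> 3 55-64         3        304.   4.81  19154. 0.0487 uncommon
#> 4 65-74         4        413. 220.      773. 0      uncommon
#> 5 75-84         4        441. 238.      815. 0      uncommon
#> 6 85+           3        844.  76.5    9317. 0      uncommon
```

Reading the output: each database contributes its own stratum rate per
100 000 person-years with an exact Poisson CI (first table); the pooled
table shows, per age group, how many databases could be pooled (`k` — cells
with fewer than 5 events or zero events drop out), the DerSimonian–Laird
pooled rate, the 95% prediction interval for a new database (much wider
than a CI whenever τ² > 0), and the CIOMS frequency class of the pooled
rate — here deep vein thrombosis in women is "uncommon" (between 1/1000 and
1/100 per person-year) across adult age groups, rising steeply with age.

`run_pipeline()` also writes `segments.csv` and `qualified_events.csv`
(per-person audit tables), the public `incidence_rates.csv` (suppressed
cells masked), `pooled_meta.csv` and a `manifest.json` whose per-outcome,
per-year exclusion tallies satisfy
`candidates = ineligible + age_excluded + sex_excluded + preindex_excluded + entrants`.

`plot_stratum_rates()` and `plot_pooled_rates()` draw the corresponding
age/sex panels.

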