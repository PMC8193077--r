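#' Aggregate at-risk segments and counted events into stratum cells
#'
#' Sums person-days and event counts within each (outcome, age group, sex)
#' cell — and database, when a `database_id` column is present — pooling the
#' index years unless `by_year = TRUE`. Person-days become person-years via
#' the configured divisor. Cells with zero person-time are omitted.
#'
#' @param segments,qualified_events The tibbles produced by
#'   [build_event_cohort()] (optionally with a `database_id` column bound
#'   on).
#' @param py_divisor Days per person-year (default 365.25).
#' @param by_year Keep index years as separate cells instead of pooling.
#' @return Tibble with the grouping keys plus `events`, `person_years`.
#' @export
stratified_counts <- function(segments, qualified_events,
                              py_divisor = 365.25, by_year = FALSE) {
  keys <- c(intersect("database_id", names(segments)),
            "outcome_id", if (by_year) "index_year", "age_group", "sex")
  days <- segments |>
    mutate(days = as.integer(as_day(.data$segment_end) -
                               as_day(.data$segment_start)) + 1L) |>
    group_by(across(all_of(keys))) |>
    summarise(person_days = sum(.data$days), .groups = "drop")
  evs <- qualified_events |>
    group_by(across(all_of(keys))) |>
    summarise(events = dplyr::n(), .groups = "drop")
  out <- days |>
    left_join(evs, by = keys) |>
    mutate(events = ifelse(is.na(.data$events), 0L, .data$events),
           person_years = .data$person_days / py_divisor) |>
    filter(.data$person_years > 0)
  orphan <- anti_join(evs, days, by = keys)
  if (nrow(orphan)) {
    abort("events recorded in a stratum with zero person-time",
          class = "bgrates_contract_error")
  }
  select(out, all_of(keys), "events", "person_years")
}

#' Incidence rate per 100 000 person-years with exact Poisson CI
#'
#' The rate is `events / person_years * 1e5`. The 95% confidence interval is
#' the exact (Garwood) Poisson interval: on the count scale the lower limit
#' is the 2.5% quantile of Gamma(events) and the upper limit the 97.5%
#' quantile of Gamma(events + 1), each divided by person-years; with zero
#' events the lower limit is 0.
#'
#' @param events Non-negative integer vector of event counts.
#' @param person_years Positive vector of person-years at risk.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `rate`, `ci_low`, `ci_high`, per 100 000 person-years.
#' @export
#' @examples
#' incidence_rate(10, 2000)   # 500 per 100 000 PY
#' incidence_rate(0, 1000)    # upper limit -ln(0.025)/1000 * 1e5
incidence_rate <- function(events, person_years, conf_level = 0.95) {
  if (any(person_years <= 0)) {
    abort("person_years must be positive", class = "bgrates_domain_error")
  }
  if (any(events < 0)) {
    abort("events must be non-negative", class = "bgrates_domain_error")
  }
  a <- (1 - conf_level) / 2
  lo <- ifelse(events == 0, 0, qgamma(a, shape = events) / person_years)
  hi <- qgamma(1 - a, shape = events + 1) / person_years
  tibble(rate = events / person_years * 1e5,
         ci_low = lo * 1e5, ci_high = hi * 1e5)
}

#' Flag small cells for suppression
#'
#' Applies the minimum-cell-count disclosure rule: by default a cell is
#' reportable when its event count reaches `min_count` (suppress when
#' `events < min_count`), the conventional reading of a minimum cell count
#' of 5. `strict_greater = TRUE` switches to the literal "exceeds" reading
#' (report only when `events > min_count`).
#'
#' @param rows Tibble with an `events` column.
#' @param min_count Minimum cell count (default 5); 0 disables suppression.
#' @param strict_greater Use `events > min_count` as the reporting rule.
#' @return `rows` with a logical `suppressed` column added.
#' @export
suppress_small_cells <- function(rows, min_count = 5, strict_greater = FALSE) {
  stopifnot(min_count >= 0)
  rows$suppressed <- if (strict_greater) rows$events <= min_count
                     else rows$events < min_count
  rows
}

#' Stratum incidence-rate table for a set of databases
#'
#' Convenience wrapper running [stratified_counts()], [incidence_rate()] and
#' [suppress_small_cells()] over the cohort outputs of each database.
#'
#' @param cohorts Named list (by `database_id`) of [build_event_cohort()]
#'   results.
#' @param py_divisor Days per person-year.
#' @param min_count Minimum cell count for suppression.
#' @param strict_greater Literal "exceeds min count" suppression rule.
#' @param by_year Report per index year instead of pooling 2017-2019.
#' @return Tibble `database_id`, `outcome_id`, `age_group`, `sex`, `events`,
#'   `person_years`, `rate`, `ci_low`, `ci_high`, `suppressed`.
#' @export
stratum_rates <- function(cohorts, py_divisor = 365.25, min_count = 5,
                          strict_greater = FALSE, by_year = FALSE) {
  counts <- imap(cohorts, function(co, id) {
    stratified_counts(
      mutate(co$segments, database_id = id),
      mutate(co$events, database_id = id),
      py_divisor = py_divisor, by_year = by_year
    )
  }) |> bind_rows()
  counts |>
    dplyr::bind_cols(incidence_rate(counts$events, counts$person_years)) |>
    suppress_small_cells(min_count = min_count, strict_greater = strict_greater)
}

#' Mask suppressed cells for public output
#'
#' Replaces event counts, rates and confidence limits of suppressed cells
#' with `NA`, keeping person-years visible. Internal (unmasked) tables are
#' retained by the pipeline for pooling-exclusion decisions only.
#'
#' @param rates Output of [stratum_rates()].
#' @return The same tibble with suppressed cells masked.
#' @export
mask_suppressed <- function(rates) {
  mutate(rates,
         events = ifelse(.data$suppressed, NA_integer_, .data$events),
         rate = ifelse(.data$suppressed, NA_real_, .data$rate),
         ci_low = ifelse(.data$suppressed, NA_real_, .data$ci_low),
         ci_high = ifelse(.data$suppressed, NA_real_, .data$ci_high))
}
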