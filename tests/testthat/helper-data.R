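# compact builders for hand-written cohort fixtures

mk_persons <- function(ids, birth_year = 1980L, sex = "female") {
  tibble::tibble(person_id = ids,
                 birth_year = rep_len(birth_year, length(ids)),
                 sex = rep_len(sex, length(ids)))
}

mk_periods <- function(ids, start, end) {
  tibble::tibble(person_id = ids,
                 start_date = as.Date(rep_len(start, length(ids))),
                 end_date = as.Date(rep_len(end, length(ids))))
}

mk_events <- function(ids, outcome, dates, setting = "outpatient",
                      position = "secondary") {
  tibble::tibble(person_id = rep_len(ids, length(dates)),
                 outcome_id = outcome,
                 event_date = as.Date(dates),
                 care_setting = rep_len(setting, length(dates)),
                 diagnosis_position = rep_len(position, length(dates)))
}

no_deaths <- tibble::tibble(person_id = character(),
                            death_date = as.Date(character()))

one_outcome <- function(id = "dvt", cw = 365L, inpatient = FALSE,
                        primary = FALSE) {
  tibble::tibble(outcome_id = id, name = id, clean_window_days = cw,
                 require_inpatient = inpatient,
                 require_primary_position = primary)
}

# random single-database fixture used by property-style tests
random_db <- function(n, seed, outcomes = default_outcome_definitions()) {
  cfg <- population_config(n, seed = seed,
                           birth_year_range = c(1925L, 2018L),
                           obs_start_window = c("2013-06-01", "2017-06-01"),
                           annual_dropout = 0.12,
                           annual_death_hazard = 0.02)
  pop <- generate_population(cfg)
  models <- default_rate_models(db_sigma = 0)
  # inflate rates so recurrent events and clean-window interactions are common
  models <- lapply(models, function(m) { m$baseline_rate <- m$baseline_rate * 40; m })
  ev <- generate_events(pop, models, seed = seed + 1L)
  list(persons = pop$persons, periods = pop$observation_periods,
       events = ev, deaths = pop$deaths)
}
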