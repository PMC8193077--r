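#' Population configuration for the synthetic generator
#'
#' Bundles and validates the demographic and observation parameters from
#' which one synthetic database population is drawn.
#'
#' @param n_persons Number of persons (non-negative integer).
#' @param birth_year_range Inclusive `c(low, high)` pair of birth years.
#' @param female_fraction Proportion of females, in `[0, 1]`.
#' @param obs_start_window `c(first, last)` calendar dates from which each
#'   person's observation start is drawn uniformly.
#' @param obs_end_date Administrative end of data capture; observation
#'   periods are truncated here.
#' @param annual_dropout Per-year probability that observation ends
#'   (dropout hazard), in `[0, 1)`.
#' @param annual_death_hazard Probability of death per person-year, in
#'   `[0, 1)`.
#' @param seed Integer seed making the population reproducible.
#' @return A list of class `bg_population_config`.
#' @export
population_config <- function(n_persons,
                              birth_year_range = c(1930L, 2015L),
                              female_fraction = 0.51,
                              obs_start_window = c("2014-01-01", "2015-12-31"),
                              obs_end_date = "2019-12-31",
                              annual_dropout = 0.05,
                              annual_death_hazard = 0.01,
                              seed = 1L) {
  if (length(n_persons) != 1 || is.na(n_persons) || n_persons < 0 ||
      n_persons != as.integer(n_persons)) {
    abort("n_persons must be a single non-negative integer",
          class = "bgrates_config_error")
  }
  if (birth_year_range[1] > birth_year_range[2]) {
    abort("birth_year_range must be an increasing pair",
          class = "bgrates_config_error")
  }
  if (female_fraction < 0 || female_fraction > 1) {
    abort("female_fraction must lie in [0, 1]", class = "bgrates_config_error")
  }
  if (annual_dropout < 0 || annual_dropout >= 1 ||
      annual_death_hazard < 0 || annual_death_hazard >= 1) {
    abort("hazards must lie in [0, 1)", class = "bgrates_config_error")
  }
  structure(list(
    n_persons = as.integer(n_persons),
    birth_year_range = as.integer(birth_year_range),
    female_fraction = female_fraction,
    obs_start_window = as.Date(obs_start_window),
    obs_end_date = as.Date(obs_end_date),
    annual_dropout = annual_dropout,
    annual_death_hazard = annual_death_hazard,
    seed = as.integer(seed)
  ), class = "bg_population_config")
}

#' Generative rate model for one outcome
#'
#' Defines the true incidence structure of one outcome in the synthetic
#' network: the true rate in a stratum of database *d* is
#' `baseline_rate * age_multiplier * sex_multiplier * exp(u_d)` with
#' `u_d ~ Normal(0, db_sigma^2)` drawn once per database (the
#' between-database heterogeneity on the natural-log rate scale).
#'
#' @param outcome_id Outcome identifier matching the outcome-definition
#'   table.
#' @param baseline_rate Events per 100 000 person-years in the reference
#'   stratum (female, age group 18-34).
#' @param age_group_multipliers Named positive vector, one multiplier per
#'   age group of [age_group_labels()].
#' @param male_multiplier Positive multiplier applied to male strata.
#' @param db_sigma Standard deviation of the database random effect on the
#'   log-rate scale (`>= 0`).
#' @param inpatient_fraction Probability an event record carries the
#'   inpatient care setting.
#' @param primary_position_fraction Probability a record carries the primary
#'   diagnosis position.
#' @return A list of class `bg_rate_model`.
#' @export
rate_model <- function(outcome_id, baseline_rate,
                       age_group_multipliers = setNames(rep(1, 8), age_group_labels()),
                       male_multiplier = 1,
                       db_sigma = 0.3,
                       inpatient_fraction = 0.2,
                       primary_position_fraction = 0.7) {
  if (baseline_rate < 0) {
    abort("baseline_rate must be non-negative", class = "bgrates_config_error")
  }
  if (!all(age_group_labels() %in% names(age_group_multipliers))) {
    abort("age_group_multipliers must name every age group",
          class = "bgrates_config_error")
  }
  if (any(age_group_multipliers <= 0) || male_multiplier <= 0) {
    abort("multipliers must be positive", class = "bgrates_config_error")
  }
  if (db_sigma < 0) abort("db_sigma must be >= 0", class = "bgrates_config_error")
  if (any(c(inpatient_fraction, primary_position_fraction) < 0) ||
      any(c(inpatient_fraction, primary_position_fraction) > 1)) {
    abort("fractions must lie in [0, 1]", class = "bgrates_config_error")
  }
  structure(list(
    outcome_id = outcome_id,
    baseline_rate = baseline_rate,
    age_group_multipliers = age_group_multipliers[age_group_labels()],
    male_multiplier = male_multiplier,
    db_sigma = db_sigma,
    inpatient_fraction = inpatient_fraction,
    primary_position_fraction = primary_position_fraction
  ), class = "bg_rate_model")
}

#' Default rate models for the fifteen AESIs
#'
#' Ground-truth generative models whose magnitudes and age/sex patterns
#' follow the broad epidemiology of each event: cardiovascular and
#' thromboembolic events rise steeply with age, anaphylaxis and appendicitis
#' peak in the young, Guillain-Barre syndrome and transverse myelitis are
#' very rare throughout. Outcomes whose cohort definition requires inpatient
#' records are generated with a high inpatient fraction.
#'
#' @param db_sigma Between-database SD of log rates shared by all outcomes
#'   (default 0.3, a substantial — roughly ±80% — database effect).
#' @return Named list of [rate_model()] objects keyed by `outcome_id`.
#' @export
default_rate_models <- function(db_sigma = 0.3) {
  ag <- age_group_labels()
  rising <- setNames(c(0.2, 0.3, 1, 4, 10, 20, 35, 50), ag)
  flat <- setNames(rep(1, 8), ag)
  young <- setNames(c(2, 3, 1.5, 1, 0.7, 0.5, 0.4, 0.3), ag)
  mild_rise <- setNames(c(0.3, 0.5, 1, 2, 3, 4, 5, 6), ag)
  tab <- list(
    list("non_haemorrhagic_stroke", 30, rising, 1.2, 0.85),
    list("haemorrhagic_stroke", 12, rising, 1.4, 0.85),
    list("acute_myocardial_infarction", 28, rising, 1.8, 0.85),
    list("deep_vein_thrombosis", 120, mild_rise, 0.9, 0.3),
    list("pulmonary_embolism", 60, mild_rise, 1.0, 0.4),
    list("anaphylaxis", 50, young, 1.0, 0.2),
    list("bell_palsy", 35, mild_rise, 1.0, 0.1),
    list("myocarditis_pericarditis", 12, mild_rise, 1.6, 0.4),
    list("narcolepsy", 8, young, 1.0, 0.1),
    list("appendicitis", 100, young, 1.2, 0.5),
    list("immune_thrombocytopenia", 6, mild_rise, 1.3, 0.3),
    list("disseminated_intravascular_coagulation", 4, mild_rise, 1.1, 0.5),
    list("encephalomyelitis", 1.5, flat, 1.0, 0.85),
    list("guillain_barre_syndrome", 2, mild_rise, 1.5, 0.9),
    list("transverse_myelitis", 1.2, flat, 1.0, 0.4)
  )
  models <- map(tab, function(s) {
    rate_model(s[[1]], baseline_rate = s[[2]], age_group_multipliers = s[[3]],
               male_multiplier = s[[4]], db_sigma = db_sigma,
               inpatient_fraction = s[[5]], primary_position_fraction = 0.7)
  })
  setNames(models, vapply(models, function(m) m$outcome_id, ""))
}

#' Generate one synthetic database population
#'
#' Draws persons, observation periods and deaths from a
#' [population_config()]. Each person has one observation period starting
#' uniformly in the configured window; its length is exponential with the
#' configured annual dropout hazard, truncated at the administrative end of
#' data capture. A death time is drawn from the annual death hazard;
#' observation is truncated at the death date and the death is recorded only
#' when it falls inside the observation period.
#'
#' @param config A [population_config()].
#' @return List of tibbles `persons`, `observation_periods`, `deaths`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "bg_population_config"))
  n <- config$n_persons
  set.seed(config$seed)
  if (n == 0) {
    return(list(
      persons = tibble(person_id = character(), birth_year = integer(),
                       sex = character()),
      observation_periods = tibble(person_id = character(),
                                   start_date = as.Date(character()),
                                   end_date = as.Date(character())),
      deaths = tibble(person_id = character(), death_date = as.Date(character()))
    ))
  }
  person_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
  birth_year <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]),
                       n, replace = TRUE)
  w <- as.integer(config$obs_start_window)
  start <- as.integer(runif(n, w[1], w[2] + 1))
  dur_days <- if (config$annual_dropout > 0) {
    as.integer(rexp(n, rate = -log(1 - config$annual_dropout)) * 365.25)
  } else {
    rep(.Machine$integer.max %/% 4L, n)
  }
  death_days <- if (config$annual_death_hazard > 0) {
    as.integer(rexp(n, rate = -log(1 - config$annual_death_hazard)) * 365.25)
  } else {
    rep(.Machine$integer.max %/% 4L, n)
  }
  end_cap <- as.integer(config$obs_end_date)
  death_day <- start + death_days
  end <- pmin(start + dur_days, end_cap, death_day)
  died <- death_day <= pmin(start + dur_days, end_cap)
  list(
    persons = tibble(person_id = person_id, birth_year = as.integer(birth_year),
                     sex = sex),
    observation_periods = tibble(
      person_id = person_id,
      start_date = as.Date(start, origin = "1970-01-01"),
      end_date = as.Date(end, origin = "1970-01-01")
    ),
    deaths = tibble(
      person_id = person_id[died],
      death_date = as.Date(death_day[died], origin = "1970-01-01")
    )
  )
}

#' Generate synthetic event records for one database
#'
#' For every person, outcome and observed calendar year, the number of events
#' is Poisson with mean equal to the true stratum rate (baseline x age
#' multiplier x sex multiplier x exp(database effect), per 100 000
#' person-years) times the person-time observed in that year. Event dates are
#' uniform within the observed part of the year; care setting and diagnosis
#' position are Bernoulli draws from the model fractions. The process runs
#' over all observed time, including time before index dates and inside
#' clean windows, so downstream exclusion logic is genuinely exercised.
#'
#' @param population Output of [generate_population()].
#' @param rate_models Named list of [rate_model()] objects.
#' @param db_effects Named numeric vector `u_d`, one log-scale random effect
#'   per outcome (names must be a subset of the rate-model names).
#' @param seed Integer seed for the event draws.
#' @return Tibble `person_id`, `outcome_id`, `event_date`, `care_setting`,
#'   `diagnosis_position`.
#' @export
generate_events <- function(population, rate_models, db_effects = NULL, seed = 1L) {
  if (is.null(db_effects)) {
    db_effects <- setNames(rep(0, length(rate_models)), names(rate_models))
  }
  unknown <- setdiff(names(db_effects), names(rate_models))
  if (length(unknown)) {
    abort(paste0("db_effects name outcomes with no rate model: ",
                 paste(unknown, collapse = ", ")),
          class = "bgrates_config_error")
  }
  per <- population$observation_periods
  persons <- population$persons
  if (nrow(per) == 0) {
    return(tibble(person_id = character(), outcome_id = character(),
                  event_date = as.Date(character()), care_setting = character(),
                  diagnosis_position = character()))
  }
  s <- as_day(per$start_date)
  e <- as_day(per$end_date)
  years <- seq(min(as.integer(format(per$start_date, "%Y"))),
               max(as.integer(format(per$end_date, "%Y"))))
  # person x calendar-year exposure cells
  cells <- map_dfr(years, function(yr) {
    lo <- pmax(s, index_day(yr))
    hi <- pmin(e, year_end_day(yr))
    keep <- lo <= hi
    tibble(person_id = per$person_id[keep], year = yr,
           obs_lo = lo[keep], obs_hi = hi[keep])
  })
  m <- match(cells$person_id, persons$person_id)
  cells$sex <- persons$sex[m]
  # years observed before age 1 (or before birth) generate no events
  cells$age_group <- age_to_group(pmax(cells$year - persons$birth_year[m], 0L))
  cells$days <- cells$obs_hi - cells$obs_lo + 1L
  # no rate model is defined below age 1: no events generated there
  cells <- cells[!is.na(cells$age_group) & cells$sex %in% .sex_levels, , drop = FALSE]

  out <- map2(rate_models, seq_along(rate_models), function(rm, oi) {
    set.seed((seed + 97L * oi) %% .Machine$integer.max)
    u <- if (rm$outcome_id %in% names(db_effects)) db_effects[[rm$outcome_id]] else 0
    rate_100k <- rm$baseline_rate *
      rm$age_group_multipliers[as.character(cells$age_group)] *
      ifelse(cells$sex == "male", rm$male_multiplier, 1) * exp(u)
    lambda <- rate_100k / 1e5 * cells$days / 365.25
    k <- rpois(nrow(cells), lambda)
    idx <- rep(seq_len(nrow(cells)), k)
    if (!length(idx)) return(NULL)
    day <- cells$obs_lo[idx] +
      as.integer(runif(length(idx)) * (cells$days[idx]))
    inp <- runif(length(idx)) < rm$inpatient_fraction
    prim <- runif(length(idx)) < rm$primary_position_fraction
    tibble(
      person_id = cells$person_id[idx],
      outcome_id = rm$outcome_id,
      event_date = as.Date(day, origin = "1970-01-01"),
      care_setting = ifelse(inp, "inpatient", "outpatient"),
      diagnosis_position = ifelse(prim, "primary", "secondary")
    )
  })
  ev <- bind_rows(out)
  if (nrow(ev) == 0) {
    ev <- tibble(person_id = character(), outcome_id = character(),
                 event_date = as.Date(character()), care_setting = character(),
                 diagnosis_position = character())
  }
  arrange(ev, .data$person_id, .data$outcome_id, .data$event_date)
}

#' Configure a synthetic multi-database network
#'
#' @param databases A list of per-database settings; each element is a list
#'   with `database_id`, `n_persons`, optional `primary_care` flag (such
#'   databases capture no inpatient records, mirroring primary-care sources),
#'   and optional overrides of [population_config()] arguments.
#' @param rate_models Named list of [rate_model()]s (default
#'   [default_rate_models()]).
#' @param seed Master seed. Per-database and per-outcome substreams are
#'   derived by fixed arithmetic on (seed, database index, outcome index), so
#'   adding a database leaves the others' draws unchanged.
#' @return List of class `bg_network_config`.
#' @export
network_config <- function(databases, rate_models = default_rate_models(),
                           seed = 1L) {
  if (length(databases) < 1) {
    abort("at least one database must be configured",
          class = "bgrates_config_error")
  }
  ids <- vapply(databases, function(d) d$database_id, "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate database_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "bgrates_config_error")
  }
  structure(list(databases = databases, rate_models = rate_models,
                 seed = as.integer(seed)),
            class = "bg_network_config")
}

#' Generate a synthetic multi-database network
#'
#' Draws independent populations for each configured database, one log-scale
#' random effect per (database, outcome) from `Normal(0, db_sigma^2)`, and
#' the event tables. Primary-care-like databases emit no inpatient-setting
#' records (events drawn as inpatient are not captured).
#'
#' @param config A [network_config()].
#' @return A list of databases; each element has `database_id`,
#'   `primary_care`, `persons`, `observation_periods`, `events`, `deaths`
#'   and `true_random_effects` (named vector of the u_d actually used).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "bg_network_config"))
  rms <- config$rate_models
  imap(setNames(config$databases,
                vapply(config$databases, function(d) d$database_id, "")),
       function(dbc, id) {
    di <- which(vapply(config$databases, function(d) d$database_id, "") == id)
    db_seed <- (config$seed + 100003L * di) %% .Machine$integer.max
    pc_args <- dbc[intersect(names(dbc), setdiff(names(formals(population_config)),
                                                 c("n_persons", "seed")))]
    pcfg <- do.call(population_config,
                    c(list(n_persons = dbc$n_persons, seed = db_seed), pc_args))
    pop <- generate_population(pcfg)
    set.seed((db_seed + 7L) %% .Machine$integer.max)
    u <- vapply(rms, function(rm) stats::rnorm(1, 0, rm$db_sigma), 0)
    names(u) <- names(rms)
    ev <- generate_events(pop, rms, db_effects = u, seed = db_seed + 13L)
    if (isTRUE(dbc$primary_care)) {
      ev <- ev[ev$care_setting != "inpatient", , drop = FALSE]
    }
    list(database_id = id,
         primary_care = isTRUE(dbc$primary_care),
         persons = pop$persons,
         observation_periods = pop$observation_periods,
         events = ev,
         deaths = pop$deaths,
         true_random_effects = u)
  })
}

#' Write a synthetic network to per-database CSV files
#'
#' Each database gets a sub-directory with `persons.csv`,
#' `observation_periods.csv`, `events.csv` and `deaths.csv` (ISO-8601 dates).
#'
#' @param network Output of [generate_network()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  for (db in network) {
    d <- file.path(dir, db$database_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(db$persons, file.path(d, "persons.csv"))
    readr::write_csv(db$observation_periods, file.path(d, "observation_periods.csv"))
    readr::write_csv(db$events, file.path(d, "events.csv"))
    readr::write_csv(db$deaths, file.path(d, "deaths.csv"))
  }
  invisible(dir)
}

#' Read a network written by [write_network()]
#'
#' @param dir Directory holding one sub-directory per database.
#' @return A list shaped like the output of [generate_network()] (without
#'   `true_random_effects`, which only the generator knows).
#' @export
read_network <- function(dir) {
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(ids)) {
    abort(paste0("no database sub-directories under ", dir),
          class = "bgrates_input_error")
  }
  setNames(map(ids, function(id) {
    d <- file.path(dir, id)
    rd <- function(f) readr::read_csv(file.path(d, f), show_col_types = FALSE)
    list(database_id = id,
         primary_care = NA,
         persons = rd("persons.csv"),
         observation_periods = rd("observation_periods.csv"),
         events = rd("events.csv"),
         deaths = rd("deaths.csv"))
  }), ids)
}
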