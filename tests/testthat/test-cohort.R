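test_that("observation periods merge overlaps and abutments, keep gaps", {
  p <- tibble::tibble(
    person_id = c("P1", "P1", "P2", "P3", "P3"),
    start_date = as.Date(c("2016-01-01", "2017-01-01", "2015-05-01",
                           "2016-01-01", "2016-09-01")),
    end_date = as.Date(c("2017-06-30", "2018-12-31", "2016-05-01",
                         "2016-06-30", "2017-12-31")))
  out <- normalise_observation(p)
  expect_equal(out[out$person_id == "P1", ]$start_date, as.Date("2016-01-01"))
  expect_equal(out[out$person_id == "P1", ]$end_date, as.Date("2018-12-31"))
  expect_equal(nrow(out[out$person_id == "P2", ]), 1)  # single interval unchanged
  expect_equal(nrow(out[out$person_id == "P3", ]), 2)  # 62-day gap preserved

  # abutting intervals (gap 0) merge too
  ab <- tibble::tibble(person_id = "A",
                       start_date = as.Date(c("2016-01-01", "2016-07-01")),
                       end_date = as.Date(c("2016-06-30", "2016-12-31")))
  expect_equal(nrow(normalise_observation(ab)), 1)

  bad <- tibble::tibble(person_id = "B", start_date = as.Date("2017-01-01"),
                        end_date = as.Date("2016-01-01"))
  expect_error(normalise_observation(bad), class = "bgrates_input_error",
               regexp = "row 1")
})

test_that("index-date eligibility needs 365 prior days within one period", {
  idx <- as.Date("2017-01-01")
  e1 <- eligible_on_index(mk_periods("P1", "2016-01-01", "2017-12-31"), idx)
  expect_true(e1$eligible)   # 366 prior days
  e2 <- eligible_on_index(mk_periods("P2", "2016-06-01", "2017-12-31"), idx)
  expect_false(e2$eligible)  # 214 prior days
  e3 <- eligible_on_index(mk_periods("P3", "2016-01-02", "2016-12-31"), idx)
  expect_false(e3$eligible)  # not observed on index
  # boundary: start exactly 365 days before index qualifies; 364 does not
  e4 <- eligible_on_index(mk_periods("P4", "2016-01-02", "2017-06-30"), idx)
  expect_true(e4$eligible)
  e5 <- eligible_on_index(mk_periods("P5", "2016-01-03", "2017-06-30"), idx)
  expect_false(e5$eligible)
})

test_that("record qualification follows inpatient / primary-position rules", {
  ev <- tibble::tibble(
    care_setting = c("outpatient", "inpatient", "inpatient"),
    diagnosis_position = c("primary", "secondary", "primary"))
  expect_equal(qualify_event(ev, one_outcome(inpatient = TRUE)),
               c(FALSE, TRUE, TRUE))
  expect_equal(qualify_event(ev, one_outcome(inpatient = TRUE, primary = TRUE)),
               c(FALSE, FALSE, TRUE))
  expect_equal(qualify_event(ev, one_outcome()), c(TRUE, TRUE, TRUE))
})

test_that("age-sex strata follow the eight-group ladder, age 0 excluded", {
  p <- mk_persons(c("A", "B", "C", "D"),
                  birth_year = c(1950L, 2017L, 1920L, 2016L),
                  sex = c("female", "male", "female", "unknown"))
  s <- assign_stratum(p, 2017L)
  expect_equal(as.character(s$age_group),
               c("65-74", NA, "85+", "1-5"))  # ages 67, 0 (excluded), 97, 1
  expect_true(is.na(s$sex[4]))
  s18 <- assign_stratum(mk_persons("E", 1920L), 2018L)
  expect_equal(as.character(s18$age_group), "85+")  # age 98, open-ended top
  expect_error(assign_stratum(mk_persons("F", 2020L), 2017L),
               class = "bgrates_input_error")
})

test_that("person-time sums closed intervals and rejects overlaps", {
  expect_equal(person_time_days(tibble::tibble(segment_start = as.Date(character()),
                                               segment_end = as.Date(character()))), 0L)
  full <- tibble::tibble(segment_start = as.Date("2017-01-01"),
                         segment_end = as.Date("2017-12-31"))
  expect_equal(person_time_days(full), 365L)
  two <- tibble::tibble(
    person_id = "P1", outcome_id = "x", index_year = 2017L,
    segment_start = as.Date(c("2017-01-01", "2017-06-01")),
    segment_end = as.Date(c("2017-04-11", "2017-12-17")))
  expect_equal(person_time_days(two), 101L + 200L)
  bad <- tibble::tibble(
    person_id = "P1", outcome_id = "x", index_year = 2017L,
    segment_start = as.Date(c("2017-01-01", "2017-03-01")),
    segment_end = as.Date(c("2017-06-30", "2017-12-31")))
  expect_error(person_time_days(bad), class = "bgrates_contract_error")
})

test_that("event-free full-year entrant contributes one 365-day segment", {
  co <- build_event_cohort(mk_persons("P1"),
                           mk_periods("P1", "2015-01-01", "2019-12-31"),
                           mk_events("P1", "dvt", as.Date(character())),
                           no_deaths, one_outcome(), index_years = 2017L)
  expect_equal(nrow(co$segments), 1)
  expect_equal(person_time_days(co$segments), 365L)
  expect_equal(nrow(co$events), 0)
})

test_that("a 365-day clean window ends the year's risk at the event", {
  co <- build_event_cohort(mk_persons("P1"),
                           mk_periods("P1", "2015-01-01", "2019-12-31"),
                           mk_events("P1", "dvt", "2017-04-11"),
                           no_deaths, one_outcome(), index_years = 2017L)
  expect_equal(nrow(co$events), 1)
  expect_equal(person_time_days(co$segments), 101L)  # Jan 1 .. Apr 11
  expect_equal(max(co$segments$segment_end), as.Date("2017-04-11"))
})

test_that("a 30-day clean window skips in-window repeats and resumes risk", {
  days <- as.Date("2017-01-01") + c(9, 24, 49)  # days 10, 25, 50 of 2017
  co <- build_event_cohort(mk_persons("P1"),
                           mk_periods("P1", "2015-01-01", "2019-12-31"),
                           mk_events("P1", "anaphylaxis", days),
                           no_deaths, one_outcome("anaphylaxis", cw = 30L),
                           index_years = 2017L)
  expect_equal(nrow(co$events), 2)  # day 25 inside the window after day 10
  expect_equal(as.integer(format(co$events$event_date, "%j")), c(10L, 50L))
  expect_equal(person_time_days(co$segments), 365L - 30L - 30L)
})

test_that("pre-index clean-window events exclude entry; index-day events count", {
  # event 100 days before index, clean window 365 -> excluded for 2017
  co <- build_event_cohort(mk_persons("P1"),
                           mk_periods("P1", "2015-01-01", "2019-12-31"),
                           mk_events("P1", "dvt", "2016-09-23"),
                           no_deaths, one_outcome(), index_years = 2017L)
  expect_equal(nrow(co$segments), 0)
  expect_equal(co$exclusions$preindex_excluded, 1L)
  expect_equal(co$exclusions$entrants, 0L)

  # same event, 30-day window -> outside the window, entry allowed
  co30 <- build_event_cohort(mk_persons("P1"),
                             mk_periods("P1", "2015-01-01", "2019-12-31"),
                             mk_events("P1", "dvt", "2016-09-23"),
                             no_deaths, one_outcome(cw = 30L),
                             index_years = 2017L)
  expect_equal(co30$exclusions$entrants, 1L)
  expect_equal(person_time_days(co30$segments), 365L)

  # event on the index date is an in-risk event on day 1, not an exclusion
  coidx <- build_event_cohort(mk_persons("P1"),
                              mk_periods("P1", "2015-01-01", "2019-12-31"),
                              mk_events("P1", "dvt", "2017-01-01"),
                              no_deaths, one_outcome(), index_years = 2017L)
  expect_equal(nrow(coidx$events), 1)
  expect_equal(person_time_days(coidx$segments), 1L)
})

test_that("a December event blocks next-year entry via its clean window", {
  co <- build_event_cohort(mk_persons("P1"),
                           mk_periods("P1", "2015-01-01", "2019-12-31"),
                           mk_events("P1", "dvt", "2017-12-15"),
                           no_deaths, one_outcome(), index_years = 2017:2018)
  ex <- co$exclusions
  expect_equal(ex$entrants[ex$index_year == 2017], 1L)
  expect_equal(ex$preindex_excluded[ex$index_year == 2018], 1L)
  # a 30-day window from the same event has expired by 1 January 2019
  co30 <- build_event_cohort(mk_persons("P1"),
                             mk_periods("P1", "2015-01-01", "2019-12-31"),
                             mk_events("P1", "dvt", "2017-11-15"),
                             no_deaths, one_outcome(cw = 30L),
                             index_years = 2018L)
  expect_equal(co30$exclusions$entrants, 1L)
})

test_that("censoring stops at observation end and death", {
  co <- build_event_cohort(mk_persons("P1"),
                           mk_periods("P1", "2015-01-01", "2017-06-30"),
                           mk_events("P1", "dvt", as.Date(character())),
                           no_deaths, one_outcome(), index_years = 2017L)
  expect_equal(person_time_days(co$segments), 181L)  # Jan 1 .. Jun 30

  dth <- tibble::tibble(person_id = "P1", death_date = as.Date("2017-03-01"))
  cod <- build_event_cohort(mk_persons("P1"),
                            mk_periods("P1", "2015-01-01", "2017-06-30"),
                            mk_events("P1", "dvt", as.Date(character())),
                            dth, one_outcome(), index_years = 2017L)
  expect_equal(max(cod$segments$segment_end), as.Date("2017-03-01"))

  # observation gap: no re-entry after the covering period ends mid-year
  gap <- tibble::tibble(person_id = "P1",
                        start_date = as.Date(c("2015-01-01", "2017-09-01")),
                        end_date = as.Date(c("2017-03-31", "2019-12-31")))
  cog <- build_event_cohort(mk_persons("P1"), gap,
                            mk_events("P1", "dvt", as.Date(character())),
                            no_deaths, one_outcome(), index_years = 2017L)
  expect_equal(person_time_days(cog$segments), 90L)
})

test_that("clean-window person-time policy switch keeps events, adds days", {
  days <- as.Date("2017-01-01") + c(9, 49)
  args <- list(mk_persons("P1"), mk_periods("P1", "2015-01-01", "2019-12-31"),
               mk_events("P1", "anaphylaxis", days), no_deaths,
               one_outcome("anaphylaxis", cw = 30L), index_years = 2017L)
  excl <- do.call(build_event_cohort, args)
  incl <- do.call(build_event_cohort, c(args, list(count_clean_window_time = TRUE)))
  expect_equal(nrow(excl$events), nrow(incl$events))
  expect_equal(person_time_days(excl$segments), 365L - 60L)
  expect_equal(person_time_days(incl$segments), 365L)
})

test_that("events of unknown outcomes are a configuration error", {
  expect_error(
    build_event_cohort(mk_persons("P1"),
                       mk_periods("P1", "2015-01-01", "2019-12-31"),
                       mk_events("P1", "mystery", "2017-05-01"),
                       no_deaths, one_outcome(), index_years = 2017L),
    class = "bgrates_config_error")
})

test_that("larger clean windows never add entrants or events; outcomes are independent", {
  db <- random_db(150, seed = 71)
  defs30 <- one_outcome("deep_vein_thrombosis", cw = 30L)
  defs365 <- one_outcome("deep_vein_thrombosis", cw = 365L)
  ev_dvt <- db$events[db$events$outcome_id == "deep_vein_thrombosis", ]
  co30 <- build_event_cohort(db$persons, db$periods, ev_dvt, db$deaths, defs30)
  co365 <- build_event_cohort(db$persons, db$periods, ev_dvt, db$deaths, defs365)
  expect_lte(sum(co365$exclusions$entrants), sum(co30$exclusions$entrants))
  expect_lte(nrow(co365$events), nrow(co30$events))

  # removing all events of other outcomes leaves this outcome untouched
  co_all <- build_event_cohort(db$persons, db$periods, db$events, db$deaths,
                               default_outcome_definitions())
  dvt_all <- co_all$segments[co_all$segments$outcome_id == "deep_vein_thrombosis", ]
  dvt_only <- co365$segments
  expect_equal(dplyr::arrange(dvt_all, person_id, index_year, segment_start),
               dplyr::arrange(dvt_only, person_id, index_year, segment_start))
})

test_that("at-risk days per person-year never exceed 365 or observed days", {
  db <- random_db(120, seed = 72)
  co <- build_event_cohort(db$persons, db$periods, db$events, db$deaths,
                           default_outcome_definitions())
  cells <- engine_cells(co)
  expect_true(all(cells$days >= 1 & cells$days <= 365))
  # observed days within the index year bound the at-risk days
  per <- normalise_observation(db$periods)
  for (i in sample(nrow(cells), min(200, nrow(cells)))) {
    yr <- cells$index_year[i]
    p <- per[per$person_id == cells$person_id[i], ]
    obs <- sum(pmax(0, as.integer(pmin(p$end_date, as.Date(sprintf("%d-12-31", yr)))) -
                      as.integer(pmax(p$start_date, as.Date(sprintf("%d-01-01", yr)))) + 1))
    expect_lte(cells$days[i], obs)
  }
})

test_that("interval algebra matches the day-by-day oracle on random data", {
  db <- random_db(200, seed = 73)
  co <- build_event_cohort(db$persons, db$periods, db$events, db$deaths,
                           default_outcome_definitions())
  got <- engine_cells(co)
  want <- oracle_cohort(db$persons, db$periods, db$events, db$deaths,
                        default_outcome_definitions())
  key <- function(d) d[order(d$person_id, d$outcome_id, d$index_year),
                       c("person_id", "outcome_id", "index_year", "days", "n_events")]
  expect_equal(key(got), key(want), ignore_attr = TRUE)
})
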