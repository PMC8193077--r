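#' Normalise observation periods
#'
#' Sorts each person's observation periods and merges intervals that overlap
#' or abut (gap of zero days). All intervals are closed on both ends.
#'
#' @param periods Data frame with columns `person_id`, `start_date`,
#'   `end_date` (Date or ISO-8601 strings).
#' @return A tibble of per-person disjoint, sorted periods with Date columns.
#' @export
#' @examples
#' normalise_observation(tibble::tibble(
#'   person_id = "P1",
#'   start_date = as.Date(c("2016-01-01", "2017-01-01")),
#'   end_date = as.Date(c("2017-06-30", "2018-12-31"))))
normalise_observation <- function(periods) {
  periods <- as_tibble(periods)
  periods$start_date <- as.Date(periods$start_date)
  periods$end_date <- as.Date(periods$end_date)
  bad <- which(periods$start_date > periods$end_date)
  if (length(bad)) {
    abort(sprintf("observation period row %d has start_date after end_date (person %s)",
                  bad[1], periods$person_id[bad[1]]),
          class = "bgrates_input_error")
  }
  if (nrow(periods) == 0) return(periods[, c("person_id", "start_date", "end_date")])
  periods |>
    arrange(.data$person_id, .data$start_date, .data$end_date) |>
    group_by(.data$person_id) |>
    mutate(
      # a new run starts where the gap to the running maximum end is > 0 days
      run = cumsum(is.na(lag(.data$end_date)) |
                     as.integer(.data$start_date) >
                       cummax(as.integer(lag(.data$end_date,
                                             default = first(.data$end_date)))) + 1L)
    ) |>
    group_by(.data$person_id, .data$run) |>
    summarise(start_date = min(.data$start_date),
              end_date = max(.data$end_date), .groups = "drop") |>
    select("person_id", "start_date", "end_date") |>
    arrange(.data$person_id, .data$start_date)
}

#' Eligibility on an index date
#'
#' A person is eligible on an index date when one of their (normalised)
#' observation periods contains the index date and began at least 365 days
#' before it, i.e. the person was continuously observed for the full prior
#' year.
#'
#' @param periods Normalised observation periods (see
#'   [normalise_observation()]).
#' @param index_date The index date (Date or ISO-8601 string); in the study
#'   design this is 1 January of each index year.
#' @return A tibble with one row per person appearing in `periods`:
#'   `person_id`, `eligible` (logical). Persons absent from `periods` are
#'   simply absent (treated as ineligible downstream).
#' @export
eligible_on_index <- function(periods, index_date) {
  idx <- as_day(index_date)
  periods |>
    as_tibble() |>
    group_by(.data$person_id) |>
    summarise(eligible = any(as_day(.data$start_date) <= idx - 365L &
                               as_day(.data$end_date) >= idx),
              .groups = "drop")
}

#' Qualify event records against an outcome definition
#'
#' A record qualifies when the outcome imposes no setting requirement, or the
#' record is from an inpatient setting and — when the primary-position rule
#' applies — carries the diagnosis in the primary position.
#'
#' @param events Data frame with columns `care_setting` (`"inpatient"` /
#'   `"outpatient"`) and `diagnosis_position` (`"primary"` / `"secondary"`).
#' @param outcome A single row of an outcome-definition table.
#' @return Logical vector, one flag per record.
#' @export
qualify_event <- function(events, outcome) {
  stopifnot(nrow(outcome) == 1)
  if (!isTRUE(outcome$require_inpatient)) return(rep(TRUE, nrow(events)))
  ok <- events$care_setting == "inpatient"
  if (isTRUE(outcome$require_primary_position)) {
    ok <- ok & events$diagnosis_position == "primary"
  }
  ok
}

#' Assign age group and sex stratum at an index year
#'
#' Age is the index year minus the year of birth, mapped to the eight age
#' groups of [age_group_labels()]. Age 0 and sexes outside male/female yield
#' `NA` strata and are excluded from cohorts (and tallied in the run
#' manifest).
#'
#' @param persons Data frame with `person_id`, `birth_year`, `sex`.
#' @param index_year Integer calendar year.
#' @return Tibble `person_id`, `age`, `age_group` (factor, `NA` when
#'   excluded), `sex` (`NA` when not male/female).
#' @export
assign_stratum <- function(persons, index_year) {
  age <- index_year - persons$birth_year
  tibble(
    person_id = persons$person_id,
    age = as.integer(age),
    age_group = age_to_group(age),
    sex = ifelse(persons$sex %in% .sex_levels, persons$sex, NA_character_)
  )
}

#' Total person-time of at-risk segments, in days
#'
#' Segments are closed intervals; a segment contributes `end - start + 1`
#' days. Segments for one (person, outcome, index year) must be disjoint.
#'
#' @param segments Data frame with `segment_start`, `segment_end` (Dates) and,
#'   when more than one row is present, `person_id`, `outcome_id`,
#'   `index_year` for the disjointness check.
#' @return Integer total days.
#' @export
person_time_days <- function(segments) {
  if (nrow(segments) == 0) return(0L)
  s <- as_day(segments$segment_start)
  e <- as_day(segments$segment_end)
  key_cols <- intersect(c("person_id", "outcome_id", "index_year"), names(segments))
  key <- if (length(key_cols)) do.call(paste, segments[key_cols]) else rep("", length(s))
  ord <- order(key, s)
  overlap <- key[ord][-1] == key[ord][-length(ord)] &
    s[ord][-1] <= e[ord][-length(ord)]
  if (any(overlap)) {
    abort("overlapping at-risk segments within one person/outcome/index year",
          class = "bgrates_contract_error")
  }
  sum(e - s + 1L)
}

# Interval-algebra walk over one person's time at risk for one outcome and
# index year. ev: sorted integer days of qualifying events inside
# [index, censor]. Returns segment bounds and counted event days.
walk_at_risk <- function(ev, index, censor, cw, count_clean_window_time = FALSE) {
  seg_start <- integer()
  seg_end <- integer()
  counted <- integer()
  pos <- index
  repeat {
    nxt <- ev[ev >= pos]
    if (!length(nxt)) {
      seg_start <- c(seg_start, pos)
      seg_end <- c(seg_end, censor)
      break
    }
    e <- nxt[1]
    seg_start <- c(seg_start, pos)
    seg_end <- c(seg_end, e)
    counted <- c(counted, e)
    pos <- e + cw + 1L
    if (pos > censor) break
  }
  if (count_clean_window_time && length(counted)) {
    # alternative person-time policy: clean-window days stay at risk, so
    # person-time is one unbroken segment; event counting is unchanged
    seg_start <- index
    seg_end <- censor
  }
  list(seg_start = seg_start, seg_end = seg_end, counted = counted)
}

#' Build per-outcome event cohorts for one database
#'
#' Implements the study design: at each 1 January index date, persons
#' observed for the prior 365 days enter the cohort of each outcome unless a
#' qualifying event of that outcome occurred during the outcome's clean
#' window before the index date. Time at risk runs from the index date until
#' the earliest of day 365 of follow-up (31 December of the index year), the
#' end of the observation period containing the index date, and death.
#' Qualifying events during time at risk are counted (a person can contribute
#' several); each counted event suspends at-risk time for the clean window,
#' after which person-time resumes. Repeat records inside a clean window are
#' not counted.
#'
#' @param persons,observation_periods,events,deaths Patient-level tables in
#'   the schema produced by [generate_population()] / [generate_events()]:
#'   `persons(person_id, birth_year, sex)`,
#'   `observation_periods(person_id, start_date, end_date)`,
#'   `events(person_id, outcome_id, event_date, care_setting,
#'   diagnosis_position)`, `deaths(person_id, death_date)`.
#' @param outcomes Outcome-definition table (see
#'   [default_outcome_definitions()]).
#' @param index_years Integer vector of index years (default 2017-2019).
#' @param count_clean_window_time Person-time policy for post-event clean
#'   windows. The default (`FALSE`) excludes clean-window days from
#'   person-time — risk resumes after the clean window; `TRUE` keeps them at
#'   risk (event counting is identical under both policies).
#' @return A list with tibbles:
#'   * `segments`: `person_id`, `outcome_id`, `index_year`, `segment_start`,
#'     `segment_end`, `age_group`, `sex`;
#'   * `events`: counted (qualified, in-risk) events with the same stratum
#'     columns;
#'   * `exclusions`: per (outcome, index year) tallies — `candidates`,
#'     `ineligible`, `age_excluded`, `sex_excluded`, `preindex_excluded`,
#'     `entrants` (the accounting identity `candidates = ineligible +
#'     age_excluded + sex_excluded + preindex_excluded + entrants` holds by
#'     construction).
#' @export
build_event_cohort <- function(persons, observation_periods, events, deaths,
                               outcomes = default_outcome_definitions(),
                               index_years = 2017:2019,
                               count_clean_window_time = FALSE) {
  persons <- as_tibble(persons)
  periods <- normalise_observation(observation_periods)
  events <- as_tibble(events)
  deaths <- as_tibble(deaths)
  if (nrow(events)) {
    unknown <- setdiff(unique(events$outcome_id), outcomes$outcome_id)
    if (length(unknown)) {
      abort(paste0("events reference outcome_id(s) absent from the outcome definitions: ",
                   paste(unknown, collapse = ", ")),
            class = "bgrates_config_error")
    }
  }

  death_day <- setNames(as_day(deaths$death_date), deaths$person_id)
  per_start <- as_day(periods$start_date)
  per_end <- as_day(periods$end_date)

  seg_out <- list()
  ev_out <- list()
  excl_out <- list()

  for (yr in index_years) {
    idx <- index_day(yr)
    # tolerant stratum assignment: ages below 1 (including records implying
    # observation before birth) are excluded and tallied, not an error
    age <- yr - persons$birth_year
    strat <- tibble(
      person_id = persons$person_id,
      age_group = age_to_group(pmax(age, 0L)),
      sex = ifelse(persons$sex %in% .sex_levels, persons$sex, NA_character_)
    )

    # containing period (periods are disjoint, so at most one)
    cover <- which(per_start <= idx & per_end >= idx)
    cover_end <- setNames(per_end[cover], periods$person_id[cover])
    cover_start <- setNames(per_start[cover], periods$person_id[cover])

    elig_ids <- names(cover_start)[cover_start <= idx - 365L]
    strat$eligible <- strat$person_id %in% elig_ids
    strat$stratum_ok <- !is.na(strat$age_group) & !is.na(strat$sex)

    censor <- pmin(idx + 364L,
                   cover_end[strat$person_id],
                   ifelse(is.na(death_day[strat$person_id]), Inf,
                          death_day[strat$person_id]))
    strat$censor <- as.integer(pmin(censor, idx + 364L))

    cand_ids <- strat$person_id[strat$eligible & strat$stratum_ok]

    for (oi in seq_len(nrow(outcomes))) {
      out_def <- outcomes[oi, ]
      cw <- out_def$clean_window_days
      oev <- events[events$outcome_id == out_def$outcome_id, , drop = FALSE]
      if (nrow(oev)) oev <- oev[qualify_event(oev, out_def), , drop = FALSE]
      ev_day <- as_day(oev$event_date)

      pre_ids <- unique(oev$person_id[ev_day >= idx - cw & ev_day <= idx - 1L])
      entrants <- setdiff(cand_ids, pre_ids)

      ent <- strat[match(entrants, strat$person_id), , drop = FALSE]

      # persons with in-risk-window events walk the interval algebra;
      # the (common) event-free entrants contribute one full segment
      in_tar <- oev$person_id %in% entrants & ev_day >= idx &
        ev_day <= ent$censor[match(oev$person_id, entrants)]
      with_ev <- unique(oev$person_id[in_tar])

      if (length(with_ev)) {
        ev_split <- split(ev_day[in_tar], oev$person_id[in_tar])
        walked <- map(with_ev, function(pid) {
          walk_at_risk(sort(ev_split[[pid]]), idx,
                       ent$censor[match(pid, entrants)], cw,
                       count_clean_window_time)
        })
        seg_w <- tibble(
          person_id = rep(with_ev, vapply(walked, function(w) length(w$seg_start), 1L)),
          segment_start = unlist(map(walked, "seg_start")),
          segment_end = unlist(map(walked, "seg_end"))
        )
        cnt_w <- tibble(
          person_id = rep(with_ev, vapply(walked, function(w) length(w$counted), 1L)),
          event_day = unlist(map(walked, "counted"))
        )
      } else {
        seg_w <- tibble(person_id = character(), segment_start = integer(),
                        segment_end = integer())
        cnt_w <- tibble(person_id = character(), event_day = integer())
      }

      no_ev <- setdiff(entrants, with_ev)
      no_ev_censor <- ent$censor[match(no_ev, entrants)]
      keep <- no_ev_censor >= idx  # a censor date before index leaves no at-risk time
      seg_all <- bind_rows(
        tibble(person_id = no_ev[keep],
               segment_start = rep(idx, sum(keep)),
               segment_end = no_ev_censor[keep]),
        seg_w
      )

      add_stratum <- function(df) {
        m <- match(df$person_id, strat$person_id)
        df$outcome_id <- out_def$outcome_id
        df$index_year <- yr
        df$age_group <- strat$age_group[m]
        df$sex <- strat$sex[m]
        df
      }
      seg_all <- add_stratum(seg_all)
      cnt_w <- add_stratum(cnt_w)

      seg_out[[length(seg_out) + 1L]] <- seg_all
      ev_out[[length(ev_out) + 1L]] <- cnt_w
      excl_out[[length(excl_out) + 1L]] <- tibble(
        outcome_id = out_def$outcome_id,
        index_year = yr,
        candidates = nrow(strat),
        ineligible = sum(!strat$eligible),
        age_excluded = sum(strat$eligible & is.na(strat$age_group)),
        sex_excluded = sum(strat$eligible & !is.na(strat$age_group) &
                             is.na(strat$sex)),
        preindex_excluded = length(intersect(pre_ids, cand_ids)),
        entrants = length(entrants)
      )
    }
  }

  segments <- bind_rows(seg_out)
  counted <- bind_rows(ev_out)
  segments$segment_start <- as.Date(segments$segment_start, origin = "1970-01-01")
  segments$segment_end <- as.Date(segments$segment_end, origin = "1970-01-01")
  counted$event_date <- as.Date(counted$event_day, origin = "1970-01-01")
  counted$event_day <- NULL
  cols <- c("person_id", "outcome_id", "index_year", "age_group", "sex")
  list(
    segments = segments |> select(all_of(c(cols[1:3], "segment_start", "segment_end",
                                           cols[4:5]))),
    events = counted |> select(all_of(c(cols[1:3], "event_date", cols[4:5]))),
    exclusions = bind_rows(excl_out)
  )
}
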