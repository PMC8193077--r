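# Brute-force day-by-day cohort simulator, written independently of the
# package's interval algebra. It re-derives eligibility, censoring and the
# clean-window rules by iterating over calendar days, and is the reference
# the fast engine must match exactly.

oracle_merge_periods <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= me + 1L) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
  }
  list(s = c(out_s, ms), e = c(out_e, me))
}

# one (person, outcome, index-year) cell; ev: integer days of qualifying
# events at any time; returns NULL when the person is not an entrant
oracle_walk_one <- function(ev, idx, censor, cw) {
  if (any(ev >= idx - cw & ev <= idx - 1L)) return(NULL)  # pre-index exclusion
  if (censor < idx) return(list(days = 0L, n_events = 0L))
  dN <- censor - idx + 1L
  evflag <- logical(dN)
  intar <- ev[ev >= idx & ev <= censor]
  evflag[intar - idx + 1L] <- TRUE
  clean_left <- 0L; days <- 0L; nev <- 0L
  for (i in seq_len(dN)) {
    if (clean_left > 0L) {
      clean_left <- clean_left - 1L
      next
    }
    days <- days + 1L
    if (evflag[i]) {
      nev <- nev + 1L
      clean_left <- cw
    }
  }
  list(days = days, n_events = nev)
}

# full-database oracle; returns one row per entrant (person, outcome, year)
oracle_cohort <- function(persons, periods, events, deaths, outcomes,
                          index_years = 2017:2019) {
  ps <- as.integer(as.Date(periods$start_date))
  pe <- as.integer(as.Date(periods$end_date))
  per_split <- split(seq_along(ps), periods$person_id)
  death_day <- stats::setNames(as.integer(as.Date(deaths$death_date)),
                               deaths$person_id)
  ev_day_all <- as.integer(as.Date(events$event_date))

  rows <- list()
  for (oi in seq_len(nrow(outcomes))) {
    od <- outcomes[oi, ]
    keep <- events$outcome_id == od$outcome_id
    if (od$require_inpatient) {
      keep <- keep & events$care_setting == "inpatient"
      if (od$require_primary_position) {
        keep <- keep & events$diagnosis_position == "primary"
      }
    }
    ev_split <- split(ev_day_all[keep], events$person_id[keep])
    for (yr in index_years) {
      idx <- as.integer(as.Date(sprintf("%d-01-01", yr)))
      for (pi in seq_len(nrow(persons))) {
        pid <- persons$person_id[pi]
        age <- yr - persons$birth_year[pi]
        if (age < 1 || !(persons$sex[pi] %in% c("male", "female"))) next
        rows_i <- per_split[[pid]]
        if (is.null(rows_i)) next
        mp <- oracle_merge_periods(ps[rows_i], pe[rows_i])
        hit <- which(mp$s <= idx & mp$e >= idx)
        if (!length(hit) || mp$s[hit] > idx - 365L) next
        censor <- min(idx + 364L, mp$e[hit],
                      if (pid %in% names(death_day)) death_day[[pid]] else Inf)
        ev <- ev_split[[pid]]
        if (is.null(ev)) ev <- integer(0)
        res <- oracle_walk_one(ev, idx, as.integer(censor), od$clean_window_days)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          person_id = pid, outcome_id = od$outcome_id, index_year = yr,
          days = res$days, n_events = res$n_events
        )
      }
    }
  }
  do.call(rbind, c(rows, list(data.frame(person_id = character(),
                                         outcome_id = character(),
                                         index_year = integer(),
                                         days = integer(),
                                         n_events = integer()))))
}

# aggregate the engine's segment/event tables to the oracle's cell grain
engine_cells <- function(cohort) {
  seg <- cohort$segments
  seg$days <- as.integer(seg$segment_end) - as.integer(seg$segment_start) + 1L
  d <- stats::aggregate(days ~ person_id + outcome_id + index_year, seg, sum)
  ev <- cohort$events
  if (nrow(ev)) {
    e <- stats::aggregate(cbind(n_events = rep(1L, nrow(ev))) ~
                            person_id + outcome_id + index_year, ev, sum)
    m <- merge(d, e, all.x = TRUE)
    m$n_events[is.na(m$n_events)] <- 0L
  } else {
    m <- d
    m$n_events <- 0L
  }
  m
}
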