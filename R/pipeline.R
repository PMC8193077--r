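#' Run configuration for the full pipeline
#'
#' Collects every analysis decision into one validated object so a run is
#' reproducible from its configuration alone. All defaults reproduce the
#' documented study behaviour: index years 2017-2019, 365-day prior
#' observation, outcome-specific clean windows, minimum cell count 5,
#' person-year divisor 365.25, clean-window days excluded from person-time.
#'
#' @param network Either a [network_config()] (synthetic run) or a directory
#'   path holding per-database CSVs as written by [write_network()].
#' @param outcomes Outcome-definition table or path to one; `NULL` for the
#'   shipped defaults.
#' @param index_years Integer vector of index years.
#' @param min_count Minimum cell count for suppression.
#' @param strict_greater Literal "exceeds min count" suppression rule.
#' @param py_divisor Days per person-year.
#' @param count_clean_window_time Person-time policy switch (see
#'   [build_event_cohort()]).
#' @param seed Master seed used for synthetic generation.
#' @param out_dir Output directory for result tables and the manifest.
#' @return List of class `bg_run_config`.
#' @export
run_config <- function(network, outcomes = NULL, index_years = 2017:2019,
                       min_count = 5, strict_greater = FALSE,
                       py_divisor = 365.25, count_clean_window_time = FALSE,
                       seed = 1L, out_dir = tempfile("bgrates_run_")) {
  if (length(index_years) == 0) {
    abort("index_years must be non-empty", class = "bgrates_config_error")
  }
  if (is.character(network) && !dir.exists(network)) {
    abort(paste0("network directory does not exist: ", network),
          class = "bgrates_config_error")
  }
  outcomes <- if (is.null(outcomes) || is.character(outcomes)) {
    load_outcome_definitions(if (is.character(outcomes)) outcomes)
  } else {
    validate_outcome_definitions(outcomes)
  }
  structure(list(
    network = network, outcomes = outcomes,
    index_years = as.integer(index_years),
    min_count = min_count, strict_greater = strict_greater,
    py_divisor = py_divisor,
    count_clean_window_time = count_clean_window_time,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "bg_run_config")
}

#' Run the full background-rate pipeline
#'
#' Orchestrates generate (or load) -> cohort construction -> stratified
#' incidence estimation -> random-effects pooling, writing each stage's
#' result before the next is computed:
#' `segments.csv`, `qualified_events.csv` (per-database audit tables),
#' `incidence_rates.csv` (public, suppressed cells masked) and
#' `pooled_meta.csv`, plus `manifest.json` echoing the configuration,
#' per-stage row counts and the person-accounting exclusion tallies.
#' Primary-care-like databases are not used for outcomes whose definition
#' requires an inpatient diagnosis. Outputs are deterministic for a fixed
#' configuration and master seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `network`, `cohorts`, `rates` (unmasked),
#'   `public_rates`, `pooled` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bg_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  network <- if (inherits(config$network, "bg_network_config")) {
    generate_network(config$network)
  } else {
    read_network(config$network)
  }

  inpatient_outcomes <- config$outcomes$outcome_id[config$outcomes$require_inpatient]
  cohorts <- map(network, function(db) {
    defs <- config$outcomes
    if (isTRUE(db$primary_care)) {
      # primary-care sources capture no hospital admissions: do not use them
      # for outcomes that require an inpatient diagnosis
      defs <- defs[!defs$require_inpatient, , drop = FALSE]
    }
    ev <- db$events[db$events$outcome_id %in% defs$outcome_id, , drop = FALSE]
    build_event_cohort(db$persons, db$observation_periods, ev,
                       db$deaths, outcomes = defs,
                       index_years = config$index_years,
                       count_clean_window_time = config$count_clean_window_time)
  })

  segments <- imap(cohorts, function(co, id) mutate(co$segments, database_id = id)) |>
    bind_rows() |> select("database_id", dplyr::everything())
  qevents <- imap(cohorts, function(co, id) mutate(co$events, database_id = id)) |>
    bind_rows() |> select("database_id", dplyr::everything())
  readr::write_csv(segments, file.path(config$out_dir, "segments.csv"))
  readr::write_csv(qevents, file.path(config$out_dir, "qualified_events.csv"))

  rates <- stratum_rates(cohorts, py_divisor = config$py_divisor,
                         min_count = config$min_count,
                         strict_greater = config$strict_greater)
  public <- mask_suppressed(rates)
  readr::write_csv(public, file.path(config$out_dir, "incidence_rates.csv"))

  pooled <- pool_rates(rates)
  readr::write_csv(pooled, file.path(config$out_dir, "pooled_meta.csv"))

  exclusions <- imap(cohorts, function(co, id) mutate(co$exclusions, database_id = id)) |>
    bind_rows()
  manifest <- list(
    package_version = as.character(utils::packageVersion("bgrates")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = list(
      index_years = config$index_years,
      min_count = config$min_count,
      strict_greater = config$strict_greater,
      py_divisor = config$py_divisor,
      count_clean_window_time = config$count_clean_window_time,
      seed = config$seed,
      synthetic = inherits(config$network, "bg_network_config")
    ),
    databases = names(network),
    row_counts = list(
      segments = nrow(segments),
      qualified_events = nrow(qevents),
      incidence_rates = nrow(rates),
      pooled_strata = nrow(pooled)
    ),
    exclusions = exclusions
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(network = network, cohorts = cohorts, rates = rates,
                 public_rates = public, pooled = pooled, manifest = manifest))
}

#' Build a run configuration from a YAML file
#'
#' Reads a YAML document with top-level keys `network` (a list of database
#' entries plus optional `seed`), `outcomes` (path, optional), and any of
#' the [run_config()] scalar options.
#'
#' @param path Path to the YAML configuration.
#' @param out_dir Output directory (overrides the file, if given).
#' @return A [run_config()].
#' @export
load_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  net <- if (is.character(y$network)) {
    y$network
  } else {
    network_config(y$network$databases, seed = y$network$seed %||% y$seed %||% 1L)
  }
  args <- y[intersect(names(y), setdiff(names(formals(run_config)),
                                        c("network", "out_dir")))]
  if (!is.null(out_dir)) args$out_dir <- out_dir
  else if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(run_config, c(list(network = net), args))
}
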