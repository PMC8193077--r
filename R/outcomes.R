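#' Default adverse-event-of-special-interest (AESI) outcome definitions
#'
#' The fifteen AESIs monitored in covid-19 vaccine safety surveillance, with
#' the clean-window length and record-qualification rules used to build event
#' cohorts. The clean window is 365 days for all outcomes except anaphylaxis
#' (30 days) and Bell's palsy and encephalomyelitis (183 days).
#' Encephalomyelitis, non-haemorrhagic stroke, haemorrhagic stroke and acute
#' myocardial infarction require an inpatient record in any diagnosis
#' position; Guillain-Barre syndrome requires an inpatient record in the
#' primary position.
#'
#' @return A tibble with columns `outcome_id`, `name`, `clean_window_days`,
#'   `require_inpatient`, `require_primary_position`, one row per AESI.
#' @export
#' @examples
#' default_outcome_definitions()
default_outcome_definitions <- function() {
  defs <- tibble::tribble(
    ~outcome_id,                    ~name,                                     ~clean_window_days, ~require_inpatient, ~require_primary_position,
    "non_haemorrhagic_stroke",      "Non-haemorrhagic stroke",                 365L, TRUE,  FALSE,
    "haemorrhagic_stroke",          "Haemorrhagic stroke",                     365L, TRUE,  FALSE,
    "acute_myocardial_infarction",  "Acute myocardial infarction",             365L, TRUE,  FALSE,
    "deep_vein_thrombosis",         "Deep vein thrombosis",                    365L, FALSE, FALSE,
    "pulmonary_embolism",           "Pulmonary embolism",                      365L, FALSE, FALSE,
    "anaphylaxis",                  "Anaphylaxis",                             30L,  FALSE, FALSE,
    "bell_palsy",                   "Bell's palsy (facial nerve palsy)",       183L, FALSE, FALSE,
    "myocarditis_pericarditis",     "Myocarditis or pericarditis",             365L, FALSE, FALSE,
    "narcolepsy",                   "Narcolepsy",                              365L, FALSE, FALSE,
    "appendicitis",                 "Appendicitis",                            365L, FALSE, FALSE,
    "immune_thrombocytopenia",      "Immune thrombocytopenia",                 365L, FALSE, FALSE,
    "disseminated_intravascular_coagulation", "Disseminated intravascular coagulation", 365L, FALSE, FALSE,
    "encephalomyelitis",            "Encephalomyelitis (incl. ADEM)",          183L, TRUE,  FALSE,
    "guillain_barre_syndrome",      "Guillain-Barre syndrome",                 365L, TRUE,  TRUE,
    "transverse_myelitis",          "Transverse myelitis",                     365L, FALSE, FALSE
  )
  validate_outcome_definitions(defs)
}

#' Load outcome definitions from a delimited file
#'
#' Reads a CSV with columns `outcome_id`, `name`, `clean_window_days`,
#' `require_inpatient`, `require_primary_position` and validates it. With no
#' path the shipped default table of fifteen AESIs is returned.
#'
#' @param path Path to a CSV file, or `NULL` for the shipped defaults.
#' @return A validated tibble of outcome definitions.
#' @export
load_outcome_definitions <- function(path = NULL) {
  if (is.null(path)) return(default_outcome_definitions())
  defs <- readr::read_csv(path, show_col_types = FALSE)
  validate_outcome_definitions(defs)
}

validate_outcome_definitions <- function(defs) {
  needed <- c("outcome_id", "name", "clean_window_days",
              "require_inpatient", "require_primary_position")
  missing <- setdiff(needed, names(defs))
  if (length(missing)) {
    abort(paste0("outcome definition table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "bgrates_input_error")
  }
  if (nrow(defs) == 0) {
    abort("outcome definition table is empty", class = "bgrates_input_error")
  }
  if (anyDuplicated(defs$outcome_id)) {
    abort(paste0("duplicate outcome_id: ",
                 paste(unique(defs$outcome_id[duplicated(defs$outcome_id)]),
                       collapse = ", ")),
          class = "bgrates_input_error")
  }
  defs$clean_window_days <- as.integer(defs$clean_window_days)
  defs$require_inpatient <- as.logical(defs$require_inpatient)
  defs$require_primary_position <- as.logical(defs$require_primary_position)
  if (any(is.na(defs$clean_window_days)) || any(defs$clean_window_days <= 0L)) {
    abort("clean_window_days must be a positive integer",
          class = "bgrates_input_error")
  }
  bad <- defs$require_primary_position & !defs$require_inpatient
  if (any(bad)) {
    abort(paste0("require_primary_position implies require_inpatient; violated by: ",
                 paste(defs$outcome_id[bad], collapse = ", ")),
          class = "bgrates_input_error")
  }
  as_tibble(defs[, needed])
}
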