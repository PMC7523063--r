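#' Cohort file dialect
#'
#' The column dictionary of the delimited-text cohort format: one row per
#' parturient encounter with the admission observation inline. Files are
#' comma-delimited UTF-8 with a header row; the missing-value token is the
#' empty string; lines starting `#` carry provenance (package version,
#' seed, config echo) and are ignored on read.
#'
#' @return Tibble with columns `column`, `type` (`character`, `numeric`,
#'   `logical`), `units`, `description`.
#' @seealso [read_cohort()], [write_cohort()]
#' @export
#' @examples
#' head(cohort_dialect())
cohort_dialect <- function() {
  cat <- ri_catalogue()
  bools <- cat$id[cat$condition == "hemorrhage" | cat$tier == "flag"]
  desc <- setNames(cat$description, cat$id)
  core <- tibble::tribble(
    ~column, ~type, ~units, ~description,
    "record_id", "character", "", "Unique record identifier",
    "district", "character", "", "Hospital/district label (cosmetic)",
    "age", "numeric", "years", "Maternal age",
    "gravida", "numeric", "count", "Number of pregnancies",
    "parity", "numeric", "count", "Number of prior births",
    "temperature", "numeric", "degC", "Admission temperature",
    "systolic_bp", "numeric", "mmHg", "Admission systolic blood pressure",
    "diastolic_bp", "numeric", "mmHg", "Admission diastolic blood pressure",
    "pulse", "numeric", "beats/min", "Admission pulse rate",
    "respiratory_rate", "numeric", "breaths/min",
      "Admission respiratory rate",
    "avpu", "character", "", "Consciousness: Alert/Voice/Pain/Unconscious",
    "urine_output", "numeric", "mL/h", "Hourly urine output",
    "urine_not_measured", "logical", "",
      "Urine output documented as not measured (scores 0)",
    "pe_awareness", "character", "",
      "Awareness: alert/agitated_confused/drowsy/difficulty_speaking/unresponsive",
    "pe_headache", "character", "", "Headache: none/mild/unrelieved",
    "pe_vision", "character", "",
      "Vision: none/blurred_impaired/temporary_blindness",
    "pe_chest_pain", "logical", "", "Chest pain",
    "pe_nausea_vomiting", "logical", "", "Nausea and vomiting",
    "pe_abdominal_pain", "logical", "", "Abdominal pain",
    "pe_proteinuria", "character", "",
      "Proteinuria: none/trace/plus1_or_300mg24h",
    "pe_platelets", "numeric", "x10^3/uL", "Platelet count",
    "pe_transaminases", "numeric", "U/L", "ASAT/ALAT",
    "pe_creatinine", "numeric", "mg/dL", "Serum creatinine",
    "pe_mgso4_respiration", "numeric", "breaths/min",
      "Respiration under MgSO4 (blank if not treated)",
    "pe_patellar_reflexes", "character", "",
      "Patellar reflexes: normal/depressed/brisk",
    "sep_altered_mental_state", "character", "",
      "Altered mental state: none/history_only/current_exam",
    "sep_needs_fio2_over_40", "logical", "",
      "Needs FiO2 > 40% to keep saturation > 92%",
    "sep_hours_without_urine", "numeric", "h", "Hours without urine",
    "sep_urine_output_ml_kg_h", "numeric", "mL/kg/h",
      "Catheter urine output (blank if no catheter)",
    "sep_skin", "character", "",
      "Skin: normal/wound_infection_signs/mottled_cyanosis_rash",
    "outcome_pph", "logical", "", "Outcome: postpartum hemorrhage",
    "outcome_infection", "logical", "", "Outcome: infection",
    "outcome_preeclampsia", "logical", "", "Outcome: preeclampsia",
    "morbidity", "logical", "",
      "Composite morbidity (OR of the outcome components)",
    "intended_positive", "logical", "",
      "Simulator ground truth: intended moderate/high class",
    "form_status", "character", "",
      "Simulator ground truth: intended form status"
  )
  boolrows <- tibble::tibble(column = bools, type = "logical", units = "",
                             description = unname(desc[bools]))
  dplyr::bind_rows(core[1:13, ], boolrows, core[14:nrow(core), ])
}

dialect_col_types <- function(columns = NULL) {
  d <- cohort_dialect()
  if (!is.null(columns)) d <- d[d$column %in% columns, ]
  cols <- purrr::map(setNames(d$type, d$column), function(ty) {
    switch(ty,
           character = readr::col_character(),
           numeric = readr::col_double(),
           logical = readr::col_logical())
  })
  do.call(readr::cols, c(cols, .default = readr::col_skip()))
}

#' Read a cohort file
#'
#' Reads and validates a delimited-text cohort written in the
#' [cohort_dialect()]: unknown columns are an error (named), enumerated
#' fields are checked value by value with the offending row and column
#' reported, and `#` provenance lines are skipped.
#'
#' @param path Path to the cohort file.
#' @return Cohort tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(study_replica_fixture(), f)
#' nrow(read_cohort(f))
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_meowsri(sprintf("Cohort file '%s' does not exist.", path),
                 "meowsri_io_error")
  }
  hdr <- readr::read_lines(path, n_max = 50)
  hdr <- hdr[!startsWith(hdr, "#")]
  if (length(hdr) == 0 || all(!nzchar(hdr))) {
    stop_meowsri("Empty cohort file.", "meowsri_io_error")
  }
  file_cols <- strsplit(hdr[1], ",")[[1]]
  file_cols <- gsub('^"|"$', "", file_cols)
  unknown <- setdiff(file_cols, cohort_dialect()$column)
  if (length(unknown)) {
    stop_meowsri(sprintf("Unknown column(s) in cohort file: %s.",
                         paste(unknown, collapse = ", ")),
                 "meowsri_io_error")
  }
  data <- readr::read_csv(path, comment = "#", na = "",
                          col_types = dialect_col_types(file_cols),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(data) == 0) {
    stop_meowsri("Empty cohort file (no records).", "meowsri_io_error")
  }
  bad_avpu <- which(!is.na(data$avpu) & !data$avpu %in% avpu_levels)
  if ("avpu" %in% names(data) && length(bad_avpu)) {
    stop_meowsri(sprintf(
      "Invalid value '%s' in column 'avpu' (row %d); allowed: %s.",
      data$avpu[bad_avpu[1]], bad_avpu[1],
      paste(avpu_levels, collapse = "/")), "meowsri_validation_error")
  }
  validate_enums(data)
  data
}

#' Write a cohort file
#'
#' Writes a cohort tibble in the [cohort_dialect()] with a provenance
#' header (`#` lines: package version, timestamp-free run metadata such as
#' the seed when supplied). Missing values are written as the empty
#' string; round-tripping through [read_cohort()] is lossless for all
#' dialect field types including missing markers.
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @param seed Optional integer recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, seed = NULL) {
  data <- tibble::as_tibble(data)
  keep <- intersect(cohort_dialect()$column, names(data))
  extra <- setdiff(names(data), cohort_dialect()$column)
  if (length(extra)) {
    inform(sprintf("write_cohort: dropping non-dialect column(s): %s.",
                   paste(extra, collapse = ", ")))
  }
  header <- c(
    sprintf("# meowsri cohort v1 (package %s)",
            as.character(utils::packageVersion("meowsri"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  readr::write_lines(header, path)
  readr::write_csv(data[, keep], path, na = "", append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
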