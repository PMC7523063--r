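# Columns the RI classifiers read, beyond the shared admission vitals.
ri_input_columns <- function() {
  cat <- ri_catalogue()
  boolean_ids <- cat$id[cat$condition == "hemorrhage" | cat$tier == "flag"]
  c(boolean_ids,
    "pe_awareness", "pe_headache", "pe_vision", "pe_chest_pain",
    "pe_nausea_vomiting", "pe_abdominal_pain", "pe_proteinuria",
    "pe_platelets", "pe_transaminases", "pe_creatinine",
    "pe_mgso4_respiration", "pe_patellar_reflexes",
    "sep_altered_mental_state", "sep_needs_fio2_over_40",
    "sep_hours_without_urine", "sep_urine_output_ml_kg_h", "sep_skin")
}

tier_code <- function(tier) {
  c(low = 1L, moderate = 2L, high = 3L)[tier]
}

#' Classify Risk Identification levels for a cohort
#'
#' Evaluates every criterion of the RI checklist against a cohort data
#' frame (one row per parturient encounter, cohort-dialect column names;
#' see [cohort_dialect()]) and grades each condition with the instrument's
#' max rule: any high-tier criterion makes the condition high risk,
#' otherwise any moderate-tier criterion makes it moderate, otherwise it
#' is low. The overall level is the maximum across the three conditions.
#' Absent or `NA` criterion fields are treated as "not present" (they
#' never fire a criterion); whether any RI input was documented at all is
#' reported in `ri_available`.
#'
#' @param data Cohort data frame.
#' @return The input as a tibble with appended columns `ri_hemorrhage`,
#'   `ri_preeclampsia`, `ri_sepsis`, `ri_overall` (ordered factors
#'   `low < moderate < high`), `ri_triggered` (list column of criterion
#'   ids, tier-bearing criteria only), `ri_flags` (list column of sepsis
#'   screening flags that fired) and `ri_available` (logical).
#' @seealso [ri_criteria()], [overall_ri()], [triage()]
#' @export
#' @examples
#' classify_risk(tibble::tibble(hem_active_bleeding = TRUE))$ri_overall
classify_risk <- function(data) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    stop_meowsri("Empty cohort: nothing to classify.",
                 "meowsri_validation_error")
  }
  validate_enums(data)
  cat <- ri_catalogue()
  fired <- vapply(seq_len(nrow(cat)), function(i) cat$predicate[[i]](data),
                  logical(nrow(data)))
  fired <- matrix(fired, nrow = nrow(data))  # n x n_criteria

  level_of <- function(cond) {
    idx <- which(cat$condition == cond & cat$tier != "flag")
    codes <- rep(1L, nrow(data))
    for (i in idx) {
      codes <- pmax(codes, ifelse(fired[, i], tier_code(cat$tier[i]), 1L))
    }
    as_risk_level(risk_levels[codes])
  }
  tiered <- which(cat$tier != "flag")
  flags <- which(cat$tier == "flag")
  data$ri_hemorrhage <- level_of("hemorrhage")
  data$ri_preeclampsia <- level_of("preeclampsia")
  data$ri_sepsis <- level_of("sepsis")
  data$ri_overall <- overall_ri(data$ri_hemorrhage, data$ri_preeclampsia,
                                data$ri_sepsis)
  data$ri_triggered <- lapply(seq_len(nrow(data)), function(r) {
    cat$id[tiered][fired[r, tiered]]
  })
  data$ri_flags <- lapply(seq_len(nrow(data)), function(r) {
    cat$id[flags][fired[r, flags]]
  })
  in_cols <- intersect(c(ri_input_columns(),
                         "systolic_bp", "diastolic_bp", "pulse",
                         "respiratory_rate", "temperature", "urine_output"),
                       names(data))
  data$ri_available <- if (length(in_cols)) {
    rowSums(!is.na(as.data.frame(data[, in_cols]))) > 0
  } else rep(FALSE, nrow(data))
  data
}

validate_enums <- function(data) {
  enums <- list(
    pe_awareness = c("alert", "agitated_confused", "drowsy",
                     "difficulty_speaking", "unresponsive"),
    pe_headache = c("none", "mild", "unrelieved"),
    pe_vision = c("none", "blurred_impaired", "temporary_blindness"),
    pe_proteinuria = c("none", "trace", "plus1_or_300mg24h"),
    pe_patellar_reflexes = c("normal", "depressed", "brisk"),
    sep_altered_mental_state = c("none", "history_only", "current_exam"),
    sep_skin = c("normal", "wound_infection_signs", "mottled_cyanosis_rash")
  )
  for (colname in intersect(names(enums), names(data))) {
    v <- data[[colname]]
    bad <- which(!is.na(v) & !v %in% enums[[colname]])
    if (length(bad)) {
      stop_meowsri(sprintf(
        "Invalid value '%s' in column '%s' (row %d); allowed: %s.",
        v[bad[1]], colname, bad[1],
        paste(enums[[colname]], collapse = ", ")),
        "meowsri_validation_error")
    }
  }
  invisible(data)
}

#' Classify a single RI condition
#'
#' Convenience wrappers around [classify_risk()] for one condition at a
#' time; each returns a tibble with the condition's risk level and the
#' criterion ids that fired.
#'
#' @param data Cohort data frame (cohort-dialect columns; absent fields
#'   count as not present).
#' @return A tibble with columns `level` (ordered factor) and `triggered`
#'   (list column of criterion ids for that condition).
#' @export
#' @examples
#' classify_hemorrhage(tibble::tibble(hem_placenta_previa_or_low_lying = TRUE))
classify_hemorrhage <- function(data) classify_condition(data, "hemorrhage")

#' @rdname classify_hemorrhage
#' @export
classify_preeclampsia <- function(data) classify_condition(data, "preeclampsia")

#' @rdname classify_hemorrhage
#' @export
classify_sepsis <- function(data) classify_condition(data, "sepsis")

classify_condition <- function(data, condition) {
  res <- classify_risk(data)
  lvl <- res[[paste0("ri_", condition)]]
  ids <- ri_catalogue()
  ids <- ids$id[ids$condition == condition & ids$tier != "flag"]
  tibble::tibble(
    level = lvl,
    triggered = lapply(res$ri_triggered, function(tr) intersect(tr, ids))
  )
}

#' Combine per-condition risk levels
#'
#' The overall RI level is the maximum of the hemorrhage, preeclampsia and
#' sepsis levels under the ordering `low < moderate < high`.
#'
#' @param hemorrhage,preeclampsia,sepsis Risk levels (character or ordered
#'   factor), recycled to a common length.
#' @return Ordered factor of overall levels.
#' @export
#' @examples
#' overall_ri("low", "high", "moderate")
overall_ri <- function(hemorrhage, preeclampsia, sepsis) {
  n <- max(length(hemorrhage), length(preeclampsia), length(sepsis))
  max_risk(rep_len(as.character(hemorrhage), n),
           rep_len(as.character(preeclampsia), n),
           rep_len(as.character(sepsis), n))
}

#' Convert a timed urine collection to an hourly rate
#'
#' The preeclampsia checklist's severe oliguria cell is a 2-hour volume
#' while the other tiers are hourly rates; this helper normalises a timed
#' collection to mL/h so one comparable unit feeds the classifiers.
#'
#' @param volume_ml Collected volume in mL.
#' @param hours Collection window in hours (> 0).
#' @return Numeric vector of hourly rates (mL/h).
#' @export
#' @examples
#' normalize_urine_output(30, hours = 2)  # 15 mL/h
normalize_urine_output <- function(volume_ml, hours) {
  if (any(!is.na(hours) & hours <= 0)) {
    stop_meowsri("`hours` must be positive.", "meowsri_validation_error")
  }
  volume_ml / hours
}
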