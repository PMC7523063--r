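# Risk Identification criteria catalogue: one row per checklist cell, with
# a vectorised predicate over the cohort dialect columns. Tier assignment
# follows the instrument with three documented repairs (see the methods
# vignette): (i) criteria printed in more than one tier take the highest
# printed tier (nausea/vomiting, abdominal pain, chest pain, ASAT/ALAT>70);
# (ii) numeric gaps between printed tiers resolve to the more severe tier
# (creatinine 0.8-0.9 and 1.1-1.2, sepsis SBP exactly 90, RR exactly 25,
# HR exactly 130, preeclampsia urine 15-30 mL/h); (iii) the preeclampsia
# DBP/HR columns are realigned to standard obstetric severity thresholds
# (DBP >=110 high, 90-109 moderate; HR >=130 high, 111-129 moderate).

crit <- function(id, condition, tier, description, predicate) {
  tibble::tibble(id = id, condition = condition, tier = tier,
                 description = description, predicate = list(predicate))
}

num_in <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
flag_on <- function(x) !is.na(x) & x
cat_in <- function(x, set) !is.na(x) & x %in% set

ri_catalogue <- function() {
  col <- function(data, name) {
    if (name %in% names(data)) data[[name]] else rep(NA, nrow(data))
  }
  bool_crit <- function(column) {
    force(column)
    function(d) flag_on(col(d, column))
  }

  hem_high <- c(
    hem_placenta_previa_or_low_lying = "Placenta previa or low-lying placenta",
    hem_suspected_accreta_percreta = "Suspected placenta accreta or percreta",
    hem_hct_below_30_with_refusal_and_other_risk =
      "Hematocrit < 30 with refusal of transfusion and other risk factors",
    hem_platelets_below_100k = "Platelets < 100,000",
    hem_active_bleeding = "Active bleeding (greater than show)",
    hem_known_coagulopathy = "Known coagulopathy"
  )
  hem_moderate <- c(
    hem_prior_cesarean_or_uterine_surgery =
      "Prior cesarean birth(s) or uterine surgery",
    hem_multiple_gestation = "Multiple gestation",
    hem_over_4_vaginal_births = "More than 4 previous vaginal births",
    hem_chorioamnionitis = "Chorioamnionitis",
    hem_prior_pph_history = "History of previous postpartum hemorrhage",
    hem_large_fibroids = "Large uterine fibroids",
    # labor/postpartum re-evaluation triggers: moderate (least-severe
    # actionable tier; the chart lists them without a tier of their own)
    hem_prolonged_second_stage = "Prolonged second-stage labor",
    hem_prolonged_oxytocin = "Prolonged oxytocin use",
    hem_magnesium_sulfate_treatment = "Magnesium sulfate treatment"
  )

  out <- list()
  for (id in names(hem_high)) {
    out[[id]] <- crit(id, "hemorrhage", "high", hem_high[[id]], bool_crit(id))
  }
  for (id in names(hem_moderate)) {
    out[[id]] <- crit(id, "hemorrhage", "moderate", hem_moderate[[id]],
                      bool_crit(id))
  }

  pe <- list(
    crit("pe_awareness_unresponsive", "preeclampsia", "high",
         "Awareness: unresponsive",
         function(d) cat_in(col(d, "pe_awareness"), "unresponsive")),
    crit("pe_awareness_altered", "preeclampsia", "moderate",
         "Awareness: agitated/confused, drowsy or difficulty speaking",
         function(d) cat_in(col(d, "pe_awareness"),
                            c("agitated_confused", "drowsy",
                              "difficulty_speaking"))),
    crit("pe_headache_unrelieved", "preeclampsia", "high",
         "Unrelieved headache",
         function(d) cat_in(col(d, "pe_headache"), "unrelieved")),
    crit("pe_headache_mild", "preeclampsia", "moderate", "Mild headache",
         function(d) cat_in(col(d, "pe_headache"), "mild")),
    crit("pe_vision_temporary_blindness", "preeclampsia", "high",
         "Temporary blindness",
         function(d) cat_in(col(d, "pe_vision"), "temporary_blindness")),
    crit("pe_vision_blurred", "preeclampsia", "moderate",
         "Blurred or impaired vision",
         function(d) cat_in(col(d, "pe_vision"), "blurred_impaired")),
    crit("pe_sbp_ge_160", "preeclampsia", "high",
         "Systolic BP >= 160 mmHg",
         function(d) num_in(col(d, "systolic_bp"), 160, Inf)),
    crit("pe_sbp_140_159", "preeclampsia", "moderate",
         "Systolic BP 140-159 mmHg",
         function(d) num_in(col(d, "systolic_bp"), 140, 159)),
    crit("pe_dbp_ge_110", "preeclampsia", "high",
         "Diastolic BP >= 110 mmHg",
         function(d) num_in(col(d, "diastolic_bp"), 110, Inf)),
    crit("pe_dbp_90_109", "preeclampsia", "moderate",
         "Diastolic BP 90-109 mmHg",
         function(d) num_in(col(d, "diastolic_bp"), 90, 109)),
    crit("pe_hr_ge_130", "preeclampsia", "high",
         "Heart rate >= 130 /min",
         function(d) num_in(col(d, "pulse"), 130, Inf)),
    crit("pe_hr_111_129", "preeclampsia", "moderate",
         "Heart rate 111-129 /min",
         function(d) num_in(col(d, "pulse"), 111, 129)),
    crit("pe_chest_pain", "preeclampsia", "high", "Chest pain",
         function(d) flag_on(col(d, "pe_chest_pain"))),
    crit("pe_rr_extreme", "preeclampsia", "high",
         "Respiratory rate < 10 or > 30 /min",
         function(d) num_in(col(d, "respiratory_rate"), 0, 9.99) |
           num_in(col(d, "respiratory_rate"), 30.01, Inf)),
    crit("pe_rr_25_30", "preeclampsia", "moderate",
         "Respiratory rate 25-30 /min",
         function(d) num_in(col(d, "respiratory_rate"), 25, 30)),
    crit("pe_nausea_vomiting", "preeclampsia", "high", "Nausea and vomiting",
         function(d) flag_on(col(d, "pe_nausea_vomiting"))),
    crit("pe_abdominal_pain", "preeclampsia", "high", "Abdominal pain",
         function(d) flag_on(col(d, "pe_abdominal_pain"))),
    crit("pe_urine_lt_30", "preeclampsia", "high",
         "Urine output < 30 mL/h (chart: <= 30 mL in 2 h)",
         function(d) num_in(col(d, "urine_output"), 0, 29.99)),
    crit("pe_urine_30_49", "preeclampsia", "moderate",
         "Urine output 30-49 mL/h",
         function(d) num_in(col(d, "urine_output"), 30, 49.99)),
    crit("pe_proteinuria", "preeclampsia", "moderate",
         "Proteinuria > +1 or 300 mg/24 h",
         function(d) cat_in(col(d, "pe_proteinuria"), "plus1_or_300mg24h")),
    crit("pe_platelets_lt_50", "preeclampsia", "high",
         "Platelets < 50 x10^3/uL",
         function(d) num_in(col(d, "pe_platelets"), 0, 49.99)),
    crit("pe_platelets_50_100", "preeclampsia", "moderate",
         "Platelets 50-100 x10^3/uL",
         function(d) num_in(col(d, "pe_platelets"), 50, 100)),
    crit("pe_transaminases_gt_70", "preeclampsia", "high",
         "ASAT/ALAT > 70 U/L",
         function(d) num_in(col(d, "pe_transaminases"), 70.01, Inf)),
    crit("pe_creatinine_gt_1_1", "preeclampsia", "high",
         "Creatinine > 1.1 mg/dL",
         function(d) num_in(col(d, "pe_creatinine"), 1.101, Inf)),
    crit("pe_creatinine_0_8_1_1", "preeclampsia", "moderate",
         "Creatinine 0.8-1.1 mg/dL",
         function(d) num_in(col(d, "pe_creatinine"), 0.8, 1.1)),
    crit("pe_mgso4_resp_lt_12", "preeclampsia", "high",
         "MgSO4 toxicity: respiration < 12 /min",
         function(d) num_in(col(d, "pe_mgso4_respiration"), 0, 11.99)),
    crit("pe_mgso4_reflex_depressed", "preeclampsia", "moderate",
         "MgSO4 toxicity: depressed patellar reflexes",
         function(d) cat_in(col(d, "pe_patellar_reflexes"), "depressed"))
  )

  sep <- list(
    # screening risk factors: recorded as flags, never raise the level
    crit("sep_risk_diabetes_comorbidity", "sepsis", "flag",
         "Gestational diabetes, diabetes or other comorbidity",
         function(d) flag_on(col(d, "sep_risk_diabetes_comorbidity"))),
    crit("sep_risk_invasive_procedure_6wk", "sepsis", "flag",
         "Invasive procedure within 6 weeks",
         function(d) flag_on(col(d, "sep_risk_invasive_procedure_6wk"))),
    crit("sep_risk_prolonged_rom", "sepsis", "flag",
         "Prolonged rupture of membranes",
         function(d) flag_on(col(d, "sep_risk_prolonged_rom"))),
    crit("sep_risk_bleeding_offensive_discharge", "sepsis", "flag",
         "Continued vaginal bleeding or offensive discharge",
         function(d) flag_on(col(d, "sep_risk_bleeding_offensive_discharge"))),
    crit("sep_ams_current", "sepsis", "high",
         "New altered mental state on examination",
         function(d) cat_in(col(d, "sep_altered_mental_state"),
                            "current_exam")),
    crit("sep_ams_history", "sepsis", "moderate",
         "History of new altered mental state",
         function(d) cat_in(col(d, "sep_altered_mental_state"),
                            "history_only")),
    crit("sep_rr_ge_25", "sepsis", "high",
         "Respiratory rate >= 25 /min",
         function(d) num_in(col(d, "respiratory_rate"), 25, Inf)),
    crit("sep_rr_21_24", "sepsis", "moderate",
         "Respiratory rate 21-24 /min",
         function(d) num_in(col(d, "respiratory_rate"), 21, 24.99)),
    crit("sep_fio2_over_40", "sepsis", "high",
         "Needs FiO2 > 40% to keep saturation > 92%",
         function(d) flag_on(col(d, "sep_needs_fio2_over_40"))),
    crit("sep_sbp_le_90", "sepsis", "high",
         "Systolic BP <= 90 mmHg",
         function(d) num_in(col(d, "systolic_bp"), 0, 90)),
    crit("sep_sbp_91_100", "sepsis", "moderate",
         "Systolic BP 91-100 mmHg",
         function(d) num_in(col(d, "systolic_bp"), 90.01, 100)),
    crit("sep_hr_ge_130", "sepsis", "high",
         "Heart rate >= 130 /min",
         function(d) num_in(col(d, "pulse"), 130, Inf)),
    crit("sep_hr_100_129", "sepsis", "moderate",
         "Heart rate 100-129 /min",
         function(d) num_in(col(d, "pulse"), 100, 129.99)),
    crit("sep_anuria_ge_18h", "sepsis", "high",
         "No urine for 18 h or more",
         function(d) num_in(col(d, "sep_hours_without_urine"), 18, Inf)),
    crit("sep_no_urine_12_18h", "sepsis", "moderate",
         "No urine for 12 to < 18 h",
         function(d) num_in(col(d, "sep_hours_without_urine"), 12, 17.99)),
    crit("sep_oliguria_lt_0_5", "sepsis", "high",
         "Catheter urine output < 0.5 mL/kg/h",
         function(d) num_in(col(d, "sep_urine_output_ml_kg_h"), 0, 0.499)),
    crit("sep_oliguria_0_5_1", "sepsis", "moderate",
         "Catheter urine output 0.5-1 mL/kg/h",
         function(d) num_in(col(d, "sep_urine_output_ml_kg_h"), 0.5, 1)),
    crit("sep_temp_gt_39", "sepsis", "high",
         "Temperature > 39 degC",
         function(d) num_in(col(d, "temperature"), 39.05, Inf)),
    crit("sep_temp_lt_36", "sepsis", "moderate",
         "Temperature < 36 degC",
         function(d) num_in(col(d, "temperature"), 0, 35.95)),
    crit("sep_skin_mottled", "sepsis", "high",
         "Mottled skin, cyanosis or non-blanching rash",
         function(d) cat_in(col(d, "sep_skin"), "mottled_cyanosis_rash")),
    crit("sep_skin_wound", "sepsis", "moderate",
         "Signs of wound/surgical-site infection",
         function(d) cat_in(col(d, "sep_skin"), "wound_infection_signs"))
  )

  dplyr::bind_rows(c(out, pe, sep))
}

#' Risk Identification criteria catalogue
#'
#' One row per checklist criterion of the RI instrument: its stable
#' identifier, the condition it belongs to (hemorrhage, preeclampsia,
#' sepsis), the tier it confers (`high`, `moderate`, or `flag` for the
#' sepsis screening risk factors that prompt assessment without raising
#' the level), and human-readable text.
#'
#' @return A tibble with columns `id`, `condition`, `tier`, `description`.
#' @seealso [classify_risk()], [recommended_response()]
#' @export
#' @examples
#' dplyr::count(ri_criteria(), condition, tier)
ri_criteria <- function() {
  ri_catalogue()[, c("id", "condition", "tier", "description")]
}

# Static response-action catalogue, transcribed from the instrument's
# Response cells (drug dosing kept as text only).
ri_responses <- function() {
  tibble::tribble(
    ~condition, ~level, ~action_id, ~action,
    "hemorrhage", "high", "consider_referral_if_not_in_labor",
      "Consider referral if not in labor",
    "hemorrhage", "high", "close_monitoring", "If in labor, close monitoring",
    "hemorrhage", "high", "type_and_screen", "Type and screen",
    "hemorrhage", "high", "order_2_units_blood", "order 2 units of blood",
    "hemorrhage", "high", "delivery", "Delivery",
    "hemorrhage", "moderate", "consider_referral_clinical_judgment",
      "Consider referral if not in labor (clinical judgment)",
    "hemorrhage", "moderate", "close_monitoring",
      "If in labor, close monitoring",
    "hemorrhage", "moderate", "type_and_screen", "Type and screen",
    "hemorrhage", "moderate", "book_2_units_blood", "Book 2 units of blood",
    "hemorrhage", "moderate", "delivery", "Delivery",
    "hemorrhage", "low", "standard_of_care", "standard of care",
    "preeclampsia", "high", "immediate_evaluation_abcde",
      "Immediate evaluation (ABCDE approach)",
    "preeclampsia", "high", "transfer_higher_acuity",
      "Transfer to higher acuity level, 1:1 staff ratio",
    "preeclampsia", "high", "antihypertensive_30min",
      "Labetalol/hydralazine within 30 min",
    "preeclampsia", "high", "mgso4_loading_or_maintenance",
      "Magnesium sulfate loading or maintenance infusion",
    "preeclampsia", "high", "oxygen_10l_rebreather",
      "O2 at 10 L per rebreather mask",
    "preeclampsia", "high", "rule_out_pulmonary_edema",
      "Rule out pulmonary edema, chest x-ray",
    "preeclampsia", "high", "safe_referral_tertiary",
      "Safe referral to tertiary center",
    "preeclampsia", "moderate", "notify_in_charge",
      "Notify in-charge RN or midwife",
    "preeclampsia", "moderate", "in_person_evaluation",
      "In-person evaluation; order labs/tests",
    "preeclampsia", "moderate", "anesthesia_consult", "Anesthesia consult",
    "preeclampsia", "moderate", "consider_mgso4",
      "Consider magnesium sulfate; supplemental oxygen",
    "preeclampsia", "moderate", "notify_physician_proteinuria",
      "Physician aware of worsening or new-onset proteinuria",
    "preeclampsia", "low", "normal_pregnancy_protocol",
      "Proceed with protocol for normal pregnancy",
    "sepsis", "high", "immediate_senior_review_abcde",
      "Immediate review by senior clinical decision maker (ABCDE approach)",
    "sepsis", "high", "sepsis_blood_panel",
      paste("Blood gas (glucose, lactate), blood culture, full blood count,",
            "CRP, urea and electrolytes, creatinine, clotting screen"),
    "sepsis", "high", "iv_antibiotics_within_1h", "IV antibiotics within 1 h",
    "sepsis", "high", "fluid_bolus_500ml",
      "500 mL bolus every 15 min, repeat up to 3 times",
    "sepsis", "high", "adrenaline_if_refractory_hypotension",
      "If SBP < 90 mmHg, adrenaline 1 mg/500 mL NS to keep MAP > 65",
    "sepsis", "high", "refer_tertiary", "Refer to a tertiary hospital",
    "sepsis", "high", "meows_monitoring", "Continue MEOWS monitoring",
    "sepsis", "moderate", "sepsis_blood_panel",
      paste("Blood gas (glucose, lactate), blood culture, full blood count,",
            "CRP, urea and electrolytes, creatinine, clotting screen"),
    "sepsis", "moderate", "senior_review_within_1h",
      "Review by senior clinical decision maker within 1 h",
    "sepsis", "moderate", "iv_antibiotics_within_1h",
      "IV antibiotics within 1 h",
    "sepsis", "moderate", "fluid_bolus_500ml",
      "500 mL bolus every 15 min, repeat up to 3 times",
    "sepsis", "moderate", "source_control_within_6h",
      "Source control within 6 h; deep infection: refer to tertiary hospital",
    "sepsis", "moderate", "hourly_reassessment",
      "If no definitive condition identified, repeat assessment hourly",
    "sepsis", "low", "clinical_judgment_care",
      "Clinical assessment; manage according to clinical judgment",
    "sepsis", "low", "meows_monitoring", "Continue MEOWS monitoring"
  )
}

#' Recommended response actions for a risk tier
#'
#' Returns the static action list from the instrument's Response cell for
#' a condition at a given risk level, as stable identifiers with
#' human-readable text.
#'
#' @param condition `"hemorrhage"`, `"preeclampsia"` or `"sepsis"`.
#' @param level `"low"`, `"moderate"` or `"high"`.
#' @return A tibble with columns `condition`, `level`, `action_id`,
#'   `action`.
#' @export
#' @examples
#' recommended_response("hemorrhage", "high")
recommended_response <- function(condition, level) {
  conditions <- c("hemorrhage", "preeclampsia", "sepsis")
  if (length(condition) != 1 || !condition %in% conditions) {
    stop_meowsri(sprintf("Unknown condition '%s'.",
                         paste(condition, collapse = ",")),
                 "meowsri_config_error")
  }
  if (length(level) != 1 || !level %in% risk_levels) {
    stop_meowsri(sprintf("Unknown risk level '%s'.",
                         paste(level, collapse = ",")),
                 "meowsri_config_error")
  }
  res <- ri_responses()
  res[res$condition == condition & res$level == level, ]
}
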