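# random single-record findings at realistic instrument precision
random_findings <- function(n) {
  maybe <- function(x, p = 0.5) ifelse(runif(n) < p, x, NA)
  tibble::tibble(
    systolic_bp = maybe(round(runif(n, 60, 200))),
    diastolic_bp = maybe(round(runif(n, 30, 130))),
    pulse = maybe(round(runif(n, 40, 160))),
    respiratory_rate = maybe(round(runif(n, 6, 40))),
    temperature = maybe(round(runif(n, 34, 41), 1)),
    urine_output = maybe(round(runif(n, 0, 120))),
    hem_placenta_previa_or_low_lying = runif(n) < 0.1,
    hem_active_bleeding = runif(n) < 0.1,
    hem_prior_cesarean_or_uterine_surgery = runif(n) < 0.2,
    hem_chorioamnionitis = runif(n) < 0.1,
    hem_prolonged_oxytocin = runif(n) < 0.15,
    pe_awareness = sample(c("alert", "agitated_confused", "drowsy",
                            "unresponsive", NA), n, replace = TRUE),
    pe_headache = sample(c("none", "mild", "unrelieved", NA), n,
                         replace = TRUE),
    pe_vision = sample(c("none", "blurred_impaired",
                         "temporary_blindness", NA), n, replace = TRUE),
    pe_chest_pain = runif(n) < 0.1,
    pe_nausea_vomiting = runif(n) < 0.15,
    pe_abdominal_pain = runif(n) < 0.15,
    pe_proteinuria = sample(c("none", "trace", "plus1_or_300mg24h", NA),
                            n, replace = TRUE),
    pe_platelets = maybe(round(runif(n, 20, 350))),
    pe_transaminases = maybe(round(runif(n, 10, 150))),
    pe_creatinine = maybe(round(runif(n, 0.3, 2), 2)),
    pe_mgso4_respiration = maybe(round(runif(n, 8, 24)), p = 0.2),
    pe_patellar_reflexes = sample(c("normal", "depressed", "brisk", NA),
                                  n, replace = TRUE),
    sep_risk_prolonged_rom = runif(n) < 0.2,
    sep_altered_mental_state = sample(c("none", "history_only",
                                        "current_exam", NA), n,
                                      replace = TRUE),
    sep_needs_fio2_over_40 = runif(n) < 0.05,
    sep_hours_without_urine = maybe(round(runif(n, 0, 24), 1)),
    sep_urine_output_ml_kg_h = maybe(round(runif(n, 0, 2), 2), p = 0.2),
    sep_skin = sample(c("normal", "wound_infection_signs",
                        "mottled_cyanosis_rash", NA), n, replace = TRUE)
  )
}

test_that("hemorrhage tiers follow the checklist", {
  expect_equal(as.character(classify_hemorrhage(
    tibble::tibble(hem_placenta_previa_or_low_lying = TRUE))$level), "high")
  expect_equal(as.character(classify_hemorrhage(
    tibble::tibble(hem_prior_cesarean_or_uterine_surgery = TRUE))$level),
    "moderate")
  expect_equal(as.character(classify_hemorrhage(
    tibble::tibble(hem_placenta_previa_or_low_lying = FALSE))$level), "low")
  # labor/postpartum re-evaluation flags are moderate-tier
  expect_equal(as.character(classify_hemorrhage(
    tibble::tibble(hem_prolonged_oxytocin = TRUE))$level), "moderate")
})

test_that("preeclampsia tiers follow the repaired threshold map", {
  one <- function(...) {
    as.character(classify_preeclampsia(tibble::tibble(...))$level)
  }
  expect_equal(one(systolic_bp = 165), "high")
  expect_equal(one(pe_platelets = 40), "high")
  expect_equal(one(pe_proteinuria = "plus1_or_300mg24h"), "moderate")
  expect_equal(one(pe_platelets = 250), "low")
  expect_equal(one(diastolic_bp = 112), "high")
  expect_equal(one(diastolic_bp = 95), "moderate")
  expect_equal(one(pulse = 120), "moderate")
  expect_equal(one(pulse = 130), "high")   # printed-gap value -> severe tier
  expect_equal(one(pe_creatinine = 1.15), "high")   # 1.1-1.2 gap -> high
  expect_equal(one(pe_creatinine = 0.85), "moderate")  # 0.8-0.9 gap -> moderate
  expect_equal(one(pe_transaminases = 80), "high")  # duplicated cell -> high
  expect_equal(one(pe_nausea_vomiting = TRUE), "high")
})

test_that("sepsis tiers follow the diagnosis criteria", {
  one <- function(...) {
    as.character(classify_sepsis(tibble::tibble(...))$level)
  }
  expect_equal(one(temperature = 39.5), "high")
  expect_equal(one(temperature = 35.5), "moderate")
  expect_equal(one(respiratory_rate = 23), "moderate")
  expect_equal(one(systolic_bp = 85), "high")
  expect_equal(one(systolic_bp = 90), "high")   # boundary -> severe tier
  expect_equal(one(systolic_bp = 95), "moderate")
  expect_equal(one(pulse = 130), "high")
  expect_equal(one(pulse = 110), "moderate")
  expect_equal(one(sep_hours_without_urine = 19), "high")
  # screening risk factors alone never raise the level
  res <- classify_risk(tibble::tibble(sep_risk_prolonged_rom = TRUE))
  expect_equal(as.character(res$ri_sepsis), "low")
  expect_true("sep_risk_prolonged_rom" %in% res$ri_flags[[1]])
})

test_that("classify_* equals the per-criterion max oracle on random records", {
  withr::local_seed(77)
  recs <- random_findings(400)
  res <- classify_risk(recs)
  for (i in seq_len(nrow(recs))) {
    rec <- as.list(recs[i, ])
    expect_equal(as.character(res$ri_hemorrhage[i]),
                 oracle_ri_condition(rec, "hemorrhage"), info = i)
    expect_equal(as.character(res$ri_preeclampsia[i]),
                 oracle_ri_condition(rec, "preeclampsia"), info = i)
    expect_equal(as.character(res$ri_sepsis[i]),
                 oracle_ri_condition(rec, "sepsis"), info = i)
  }
})

test_that("adding a true criterion never lowers a level", {
  withr::local_seed(88)
  recs <- random_findings(100)
  base <- classify_risk(recs)
  bumped <- recs
  bumped$hem_chorioamnionitis <- TRUE
  res <- classify_risk(bumped)
  expect_true(all(res$ri_hemorrhage >= base$ri_hemorrhage))
  expect_true(all(res$ri_overall >= base$ri_overall))
})

test_that("every triggered id maps to exactly one catalogue entry", {
  withr::local_seed(99)
  recs <- random_findings(200)
  res <- classify_risk(recs)
  cat <- ri_criteria()
  expect_false(any(duplicated(cat$id)))
  ids <- unique(unlist(res$ri_triggered))
  expect_true(all(ids %in% cat$id))
  # any record above low has at least one triggered criterion
  above <- as.character(res$ri_overall) != "low"
  expect_true(all(lengths(res$ri_triggered)[above] > 0))
})

test_that("overall_ri is the max and behaves like one", {
  expect_equal(as.character(overall_ri("low", "low", "low")), "low")
  expect_equal(as.character(overall_ri("low", "high", "low")), "high")
  expect_equal(as.character(overall_ri("moderate", "low", "moderate")),
               "moderate")
  lv <- c("low", "moderate", "high")
  for (a in lv) for (b in lv) for (c in lv) {
    # commutative in all arguments, idempotent on equal inputs
    expect_equal(overall_ri(a, b, c), overall_ri(c, a, b))
    expect_equal(as.character(overall_ri(a, a, a)), a)
    # associative through pairwise folding
    ab <- as.character(overall_ri(a, b, "low"))
    expect_equal(overall_ri(ab, c, "low"), overall_ri(a, b, c))
  }
})

test_that("response catalogue matches the instrument's response cells", {
  expect_true("order_2_units_blood" %in%
                recommended_response("hemorrhage", "high")$action_id)
  expect_true("iv_antibiotics_within_1h" %in%
                recommended_response("sepsis", "moderate")$action_id)
  expect_identical(recommended_response("hemorrhage", "low")$action,
                   "standard of care")
  expect_error(recommended_response("cardiac", "high"),
               class = "meowsri_config_error")
})

test_that("invalid enumerated values are rejected with row and column", {
  expect_error(
    classify_risk(tibble::tibble(pe_headache = "terrible")),
    regexp = "pe_headache.*row 1",
    class = "meowsri_validation_error")
})

test_that("timed urine collections normalise to hourly rates", {
  expect_equal(normalize_urine_output(30, 2), 15)
  expect_equal(normalize_urine_output(c(60, 100), c(2, 4)), c(30, 25))
  expect_error(normalize_urine_output(30, 0),
               class = "meowsri_validation_error")
})
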