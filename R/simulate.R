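#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the simulator parameters. Defaults are the study
#' conditions of the instrument's district-hospital implementation: 10.3%
#' composite-morbidity prevalence, a moderate/high-vs-low predictor
#' operating at 28.9% sensitivity and 93.5% specificity, and bedside-form
#' completeness fractions 363/478, 79/478, 36/478
#' (completed/partial/empty).
#'
#' @param n Cohort size (>= 1).
#' @param prevalence Morbidity probability in `[0, 1]`.
#' @param target_sensitivity,target_specificity Operating point of the
#'   intended triage class given morbidity status.
#' @param completeness_probs Length-3 numeric (completed, partial, empty)
#'   summing to 1.
#' @param missing_field_rate Per-field masking probability for the
#'   demographic fields of partial forms (at least one field is always
#'   masked so the form is genuinely partial).
#' @param mechanism_probs Length-4 numeric mixing proportions over the
#'   source of positivity (hemorrhage, preeclampsia, sepsis, meows),
#'   uniform by default.
#' @param seed Integer seed; mandatory, recorded in the cohort header by
#'   [write_cohort()].
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(n = 100, seed = 1)
cohort_config <- function(n,
                          prevalence = 49 / 478,
                          target_sensitivity = 13 / 45,
                          target_specificity = 331 / 354,
                          completeness_probs = c(363, 79, 36) / 478,
                          missing_field_rate = 0.5,
                          mechanism_probs = rep(0.25, 4),
                          seed) {
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    stop_meowsri("`seed` is mandatory for reproducibility.",
                 "meowsri_validation_error")
  }
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop_meowsri("`n` must be a single integer >= 1.",
                 "meowsri_validation_error")
  }
  check_prob(prevalence, "prevalence")
  check_prob(target_sensitivity, "target_sensitivity")
  check_prob(target_specificity, "target_specificity")
  check_prob(missing_field_rate, "missing_field_rate")
  if (length(completeness_probs) != 3 ||
      abs(sum(completeness_probs) - 1) > 1e-9 ||
      any(completeness_probs < 0)) {
    stop_meowsri(
      "`completeness_probs` must be 3 non-negative numbers summing to 1.",
      "meowsri_validation_error")
  }
  if (length(mechanism_probs) != 4 || any(mechanism_probs < 0) ||
      sum(mechanism_probs) <= 0) {
    stop_meowsri("`mechanism_probs` must be 4 non-negative weights.",
                 "meowsri_validation_error")
  }
  structure(list(
    n = as.integer(n), prevalence = prevalence,
    target_sensitivity = target_sensitivity,
    target_specificity = target_specificity,
    completeness_probs = completeness_probs,
    missing_field_rate = missing_field_rate,
    mechanism_probs = mechanism_probs / sum(mechanism_probs),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

districts <- function() c("Kibagabaga", "Muhima", "Kabutare", "Nyanza")
district_probs <- function() c(0.282, 0.285, 0.291, 0.136) / 0.994

# Baseline record: vitals in the MEOWS 0-bands restricted so that no RI
# criterion fires either (e.g. SBP >= 101 avoids the sepsis 91-100 band,
# pulse <= 99 the sepsis 100-129 band, urine >= 50 the preeclampsia
# 30-49 band), checklists clear, labs normal.
cohort_baseline <- function(n) {
  cat <- ri_catalogue()
  out <- tibble::tibble(
    record_id = sprintf("R%04d", seq_len(n)),
    district = sample(districts(), n, replace = TRUE,
                      prob = district_probs()),
    age = pmin(pmax(round(rnorm(n, 28.30, 6.38)), 15), 49),
    gravida = pmin(pmax(round(rnorm(n, 2.58, 1.91)), 0), 12),
    parity = pmin(pmax(round(rnorm(n, 1.43, 1.67)), 0), 10),
    temperature = round(runif(n, 36.0, 37.4), 1),
    systolic_bp = round(runif(n, 101, 139)),
    diastolic_bp = round(runif(n, 46, 89)),
    pulse = round(runif(n, 51, 99)),
    respiratory_rate = round(runif(n, 15, 20)),
    avpu = rep("Alert", n),
    urine_output = round(runif(n, 50, 120)),
    urine_not_measured = rep(FALSE, n)
  )
  for (id in cat$id[cat$condition == "hemorrhage" | cat$tier == "flag"]) {
    out[[id]] <- rep(FALSE, n)
  }
  out$pe_awareness <- rep("alert", n)
  out$pe_headache <- rep("none", n)
  out$pe_vision <- rep("none", n)
  out$pe_chest_pain <- rep(FALSE, n)
  out$pe_nausea_vomiting <- rep(FALSE, n)
  out$pe_abdominal_pain <- rep(FALSE, n)
  out$pe_proteinuria <- rep("none", n)
  out$pe_platelets <- round(runif(n, 150, 350))
  out$pe_transaminases <- round(runif(n, 15, 45))
  out$pe_creatinine <- round(runif(n, 0.4, 0.75), 2)
  out$pe_mgso4_respiration <- rep(NA_real_, n)
  out$pe_patellar_reflexes <- rep("normal", n)
  out$sep_altered_mental_state <- rep("none", n)
  out$sep_needs_fio2_over_40 <- rep(FALSE, n)
  out$sep_hours_without_urine <- round(runif(n, 0, 8), 1)
  out$sep_urine_output_ml_kg_h <- rep(NA_real_, n)
  out$sep_skin <- rep("normal", n)
  out$outcome_pph <- rep(FALSE, n)
  out$outcome_infection <- rep(FALSE, n)
  out$outcome_preeclampsia <- rep(FALSE, n)
  out$morbidity <- rep(FALSE, n)
  out$intended_positive <- rep(FALSE, n)
  out$form_status <- rep("completed", n)
  out
}

#' Generate a synthetic parturient cohort
#'
#' Class-first (inverse) generation: each record first draws its latent
#' morbidity (`Bernoulli(prevalence)`) and its intended triage class
#' (positive with probability `target_sensitivity` given morbidity,
#' `1 - target_specificity` otherwise), then receives vital signs and
#' checklist values constructed to realise that class exactly. Negative
#' records get vitals inside the MEOWS 0/1-point bands and all-clear
#' checklists (total <= 1, every RI condition low); positive records get
#' one firing source drawn from `mechanism_probs` — a hemorrhage checklist
#' criterion, a preeclampsia laboratory/symptom criterion, a sepsis
#' diagnostic criterion, or a vital-sign pattern with MEOWS total 3.
#' Running the package's own scorer and classifiers on the generated
#' columns therefore reproduces the intended class for every record whose
#' form is not empty.
#'
#' Form statuses are then assigned from `completeness_probs`; partial
#' forms mask demographic fields only (so masking can never change the
#' triage class), empty forms mask every form and checklist field and are
#' excluded by [triage()] as unclassifiable. Morbid records receive one
#' outcome component (PPH, infection or preeclampsia) uniformly; the
#' latent columns `morbidity` and `intended_positive` are retained as
#' simulation ground truth and never masked.
#'
#' @param config A [cohort_config()] object.
#' @return Cohort tibble in the cohort dialect (see [cohort_dialect()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 42))
#' dplyr::count(cohort, intended_positive, morbidity)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_meowsri("`config` must be a `cohort_config` object.",
                 "meowsri_validation_error")
  }
  set.seed(config$seed)
  n <- config$n
  out <- cohort_baseline(n)

  morbid <- runif(n) < config$prevalence
  positive <- ifelse(morbid,
                     runif(n) < config$target_sensitivity,
                     runif(n) < 1 - config$target_specificity)
  out$morbidity <- morbid
  out$intended_positive <- positive

  # outcome components for morbid records
  comp <- sample(c("outcome_pph", "outcome_infection",
                   "outcome_preeclampsia"), n, replace = TRUE)
  for (cc in c("outcome_pph", "outcome_infection", "outcome_preeclampsia")) {
    out[[cc]] <- morbid & comp == cc
  }

  # a third of negatives carry one harmless 1-point component so that low
  # records are not uniformly zero
  tweak <- which(!positive & runif(n) < 1 / 3)
  if (length(tweak)) {
    kind <- sample(3, length(tweak), replace = TRUE)
    i <- tweak[kind == 1]
    out$temperature[i] <- round(runif(length(i), 37.5, 38.9), 1)
    i <- tweak[kind == 2]
    out$respiratory_rate[i] <- round(runif(length(i), 11, 14))
    i <- tweak[kind == 3]
    out$pulse[i] <- round(runif(length(i), 42, 50))
  }

  # positives: draw the firing mechanism
  pos <- which(positive)
  if (length(pos)) {
    mech <- sample(c("hemorrhage", "preeclampsia", "sepsis", "meows"),
                   length(pos), replace = TRUE,
                   prob = config$mechanism_probs)
    hem_ids <- ri_catalogue()
    hem_ids <- hem_ids$id[hem_ids$condition == "hemorrhage"]
    i <- pos[mech == "hemorrhage"]
    if (length(i)) {
      pick <- sample(hem_ids, length(i), replace = TRUE)
      for (id in unique(pick)) out[[id]][i[pick == id]] <- TRUE
    }
    i <- pos[mech == "preeclampsia"]
    if (length(i)) {
      pick <- sample(6, length(i), replace = TRUE)
      j <- i[pick == 1]; out$pe_platelets[j] <- round(runif(length(j), 20, 45))
      j <- i[pick == 2]; out$pe_platelets[j] <- round(runif(length(j), 55, 95))
      j <- i[pick == 3]; out$pe_proteinuria[j] <- "plus1_or_300mg24h"
      j <- i[pick == 4]; out$pe_headache[j] <- "mild"
      j <- i[pick == 5]
      out$pe_transaminases[j] <- round(runif(length(j), 80, 150))
      j <- i[pick == 6]
      out$pe_creatinine[j] <- round(runif(length(j), 1.3, 2.0), 2)
    }
    i <- pos[mech == "sepsis"]
    if (length(i)) {
      pick <- sample(6, length(i), replace = TRUE)
      j <- i[pick == 1]
      out$temperature[j] <- round(runif(length(j), 39.2, 40.5), 1)
      j <- i[pick == 2]
      out$temperature[j] <- round(runif(length(j), 35.1, 35.9), 1)
      j <- i[pick == 3]
      out$sep_hours_without_urine[j] <- round(runif(length(j), 19, 24), 1)
      j <- i[pick == 4]
      out$sep_hours_without_urine[j] <- round(runif(length(j), 13, 17), 1)
      j <- i[pick == 5]; out$sep_skin[j] <- "wound_infection_signs"
      j <- i[pick == 6]; out$sep_skin[j] <- "mottled_cyanosis_rash"
    }
    i <- pos[mech == "meows"]
    if (length(i)) {
      # three harmless 1-point components: total 3 -> review tier, no RI
      # criterion involved
      out$temperature[i] <- round(runif(length(i), 37.6, 38.9), 1)
      out$respiratory_rate[i] <- round(runif(length(i), 11, 14))
      out$pulse[i] <- round(runif(length(i), 42, 50))
    }
  }

  # form status and masking (after classification inputs are fixed)
  status <- sample(c("completed", "partial", "empty"), n, replace = TRUE,
                   prob = config$completeness_probs)
  out$form_status <- status
  demo <- c("age", "gravida", "parity")
  part <- which(status == "partial")
  for (i in part) {
    mask <- demo[runif(3) < config$missing_field_rate]
    if (length(mask) == 0) mask <- sample(demo, 1)
    for (f in mask) out[[f]][i] <- NA
  }
  maskable <- c(demo, "temperature", "systolic_bp", "diastolic_bp", "pulse",
                "respiratory_rate", "avpu", "urine_output",
                "urine_not_measured", ri_input_columns())
  emp <- which(status == "empty")
  for (f in intersect(maskable, names(out))) out[[f]][emp] <- NA
  out
}

#' Deterministic study-replica cohort
#'
#' A fixed 478-record cohort reproducing the marginal structure of the
#' instrument's district-hospital implementation: form statuses exactly
#' 363 completed / 79 partial / 36 empty; 49 morbid records (prevalence
#' 10.3%); and 399 records with complete predictor and outcome data whose
#' triage-by-morbidity cross-tabulation is exactly
#' (tp, fp, fn, tn) = (13, 23, 32, 331). The 79 non-analyzable records
#' split into the 36 empty forms and 43 partial forms lacking all
#' predictor fields; a further 36 partial forms miss only a demographic
#' field and remain analyzable (363 + 36 = 399).
#'
#' The fixture is synthetic: record-level values are constructed (no
#' random draws), only the published margins are real.
#'
#' @return Cohort tibble of 478 records.
#' @export
#' @examples
#' ev <- evaluate_cohort(study_replica_fixture())
#' ev$contingency
study_replica_fixture <- function() {
  n <- 478
  # template for column set/types; every stochastic column is overwritten
  # below with fixed values, and the caller's RNG state is left untouched
  rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  base <- cohort_baseline(1)
  if (!is.null(rng)) assign(".Random.seed", rng, globalenv())
  out <- tibble::tibble(record_id = sprintf("F%04d", seq_len(n)))
  for (col in setdiff(names(base), "record_id")) {
    out[[col]] <- rep(base[[col]][1], n)
  }
  out$district <- rep(districts(), length.out = n)
  out$age <- rep(28, n); out$gravida <- rep(3, n); out$parity <- rep(1, n)
  out$temperature <- rep(36.8, n); out$systolic_bp <- rep(118, n)
  out$diastolic_bp <- rep(72, n); out$pulse <- rep(76, n)
  out$respiratory_rate <- rep(16, n); out$avpu <- rep("Alert", n)
  out$urine_output <- rep(60, n)
  out$pe_platelets <- rep(250, n); out$pe_transaminases <- rep(30, n)
  out$pe_creatinine <- rep(0.6, n)
  out$sep_hours_without_urine <- rep(2, n)

  # 36 analyzable positives (rows 1-36): 13 morbid, 23 not; mechanism
  # cycles over the four firing sources
  pos <- 1:36
  mech <- rep(c("hemorrhage", "preeclampsia", "sepsis", "meows"),
              length.out = 36)
  i <- pos[mech == "hemorrhage"]
  out$hem_placenta_previa_or_low_lying[i] <- TRUE
  i <- pos[mech == "preeclampsia"]
  out$pe_platelets[i] <- 40
  i <- pos[mech == "sepsis"]
  out$temperature[i] <- 39.5
  i <- pos[mech == "meows"]
  out$temperature[i] <- 38.0
  out$respiratory_rate[i] <- 12
  out$pulse[i] <- 45

  morbid <- c(1:13, 37:68, 400:403)  # 13 + 32 + 4 = 49
  out$morbidity[morbid] <- TRUE
  out$outcome_pph[morbid] <- TRUE
  out$intended_positive[pos] <- TRUE

  # form statuses: rows 1-36 partial (demographic missing, analyzable),
  # 37-399 completed, 400-442 partial (predictor missing, excluded),
  # 443-478 empty
  out$age[1:36] <- NA
  out$form_status[1:36] <- "partial"
  excl_partial <- 400:442
  empty <- 443:478
  clinical <- c("temperature", "systolic_bp", "diastolic_bp", "pulse",
                "respiratory_rate", "avpu", "urine_output",
                "urine_not_measured", ri_input_columns())
  for (f in clinical) out[[f]][excl_partial] <- NA
  out$form_status[excl_partial] <- "partial"
  for (f in c("age", "gravida", "parity", clinical)) out[[f]][empty] <- NA
  out$form_status[empty] <- "empty"
  out$intended_positive[c(excl_partial, empty)] <- NA
  out
}
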