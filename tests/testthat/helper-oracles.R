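# Independent oracles: literal if/else transcriptions of the instrument,
# deliberately sharing no code with the package implementation.

oracle_component <- function(parameter, value) {
  if (is.na(value)) return(NA_integer_)
  v <- if (parameter == "temperature") round(value * 10) / 10 else round(value)
  switch(parameter,
    temperature = {
      if (v < 35) 2L
      else if (v <= 37.4) 0L
      else if (v <= 39.0) 1L
      else 2L
    },
    systolic_bp = {
      if (v <= 70) 3L
      else if (v <= 80) 2L
      else if (v <= 89) 1L
      else if (v <= 139) 0L
      else if (v <= 149) 1L
      else if (v <= 159) 2L
      else 3L
    },
    diastolic_bp = {
      if (v <= 45) 2L
      else if (v <= 89) 0L
      else if (v <= 99) 1L
      else if (v <= 109) 2L
      else 3L
    },
    pulse = {
      if (v <= 40) 2L
      else if (v <= 50) 1L
      else if (v <= 100) 0L
      else if (v <= 110) 1L
      else if (v <= 129) 2L
      else 3L
    },
    respiratory_rate = {
      if (v <= 8) 3L
      else if (v <= 14) 1L
      else if (v <= 20) 0L
      else if (v <= 29) 2L
      else 3L
    },
    urine_output = {
      if (v < 10) 3L
      else if (v < 30) 2L
      else 0L
    },
    stop("unknown parameter")
  )
}

oracle_avpu <- function(value) {
  if (is.na(value)) return(NA_integer_)
  c(Alert = 0L, Voice = 1L, Pain = 2L, Unconscious = 3L)[[value]]
}

# Brute-force MEOWS for a single observation given as a named list.
oracle_meows <- function(obs) {
  s <- c(
    temperature = oracle_component("temperature", obs$temperature),
    systolic_bp = oracle_component("systolic_bp", obs$systolic_bp),
    diastolic_bp = oracle_component("diastolic_bp", obs$diastolic_bp),
    pulse = oracle_component("pulse", obs$pulse),
    respiratory_rate = oracle_component("respiratory_rate",
                                        obs$respiratory_rate),
    avpu = oracle_avpu(obs$avpu),
    urine_output = if (isTRUE(obs$urine_not_measured)) 0L else
      oracle_component("urine_output", obs$urine_output)
  )
  if (!is.na(obs$pulse) && !is.na(obs$systolic_bp) &&
      obs$pulse > obs$systolic_bp && !is.na(s[["pulse"]])) {
    s[["pulse"]] <- max(s[["pulse"]], 2L)
  }
  total <- if (all(is.na(s))) NA_integer_ else sum(s, na.rm = TRUE)
  trigger <- if (is.na(total)) NA_character_
             else if (total <= 2) "current_plan"
             else if (total <= 5) "review"
             else "escalate"
  list(scores = s, total = total, trigger = trigger)
}

# Random vital-sign observations over the full admissible domains, with
# optional missingness.
random_observations <- function(n, p_missing = 0.1) {
  miss <- function(x) ifelse(runif(n) < p_missing, NA, x)
  tibble::tibble(
    temperature = miss(round(runif(n, 25, 45), 1)),
    systolic_bp = miss(round(runif(n, 0, 300))),
    diastolic_bp = miss(round(runif(n, 0, 200))),
    pulse = miss(round(runif(n, 0, 300))),
    respiratory_rate = miss(round(runif(n, 0, 100))),
    avpu = miss(sample(c("Alert", "Voice", "Pain", "Unconscious"), n,
                       replace = TRUE)),
    urine_output = miss(round(runif(n, 0, 1000))),
    urine_not_measured = runif(n) < 0.05
  )
}

# Per-criterion max-rule oracle for the RI conditions: evaluates every
# criterion of a single record independently and takes the highest tier.
oracle_ri_condition <- function(rec, condition) {
  g <- function(f) if (!is.null(rec[[f]]) && !is.na(rec[[f]])) rec[[f]] else NA
  tiers <- character()
  hit <- function(cond, tier) tiers <<- c(tiers, tier)
  if (condition == "hemorrhage") {
    high <- c("hem_placenta_previa_or_low_lying",
              "hem_suspected_accreta_percreta",
              "hem_hct_below_30_with_refusal_and_other_risk",
              "hem_platelets_below_100k", "hem_active_bleeding",
              "hem_known_coagulopathy")
    mod <- c("hem_prior_cesarean_or_uterine_surgery",
             "hem_multiple_gestation", "hem_over_4_vaginal_births",
             "hem_chorioamnionitis", "hem_prior_pph_history",
             "hem_large_fibroids", "hem_prolonged_second_stage",
             "hem_prolonged_oxytocin", "hem_magnesium_sulfate_treatment")
    for (f in high) if (isTRUE(g(f))) hit(condition, "high")
    for (f in mod) if (isTRUE(g(f))) hit(condition, "moderate")
  } else if (condition == "preeclampsia") {
    aw <- g("pe_awareness")
    if (identical(aw, "unresponsive")) hit(condition, "high")
    if (aw %in% c("agitated_confused", "drowsy", "difficulty_speaking")) {
      hit(condition, "moderate")
    }
    hd <- g("pe_headache")
    if (identical(hd, "unrelieved")) hit(condition, "high")
    if (identical(hd, "mild")) hit(condition, "moderate")
    vi <- g("pe_vision")
    if (identical(vi, "temporary_blindness")) hit(condition, "high")
    if (identical(vi, "blurred_impaired")) hit(condition, "moderate")
    sbp <- g("systolic_bp")
    if (!is.na(sbp) && sbp >= 160) hit(condition, "high")
    if (!is.na(sbp) && sbp >= 140 && sbp <= 159) hit(condition, "moderate")
    dbp <- g("diastolic_bp")
    if (!is.na(dbp) && dbp >= 110) hit(condition, "high")
    if (!is.na(dbp) && dbp >= 90 && dbp <= 109) hit(condition, "moderate")
    hr <- g("pulse")
    if (!is.na(hr) && hr >= 130) hit(condition, "high")
    if (!is.na(hr) && hr >= 111 && hr <= 129) hit(condition, "moderate")
    if (isTRUE(g("pe_chest_pain"))) hit(condition, "high")
    rr <- g("respiratory_rate")
    if (!is.na(rr) && (rr < 10 || rr > 30)) hit(condition, "high")
    if (!is.na(rr) && rr >= 25 && rr <= 30) hit(condition, "moderate")
    if (isTRUE(g("pe_nausea_vomiting"))) hit(condition, "high")
    if (isTRUE(g("pe_abdominal_pain"))) hit(condition, "high")
    uo <- g("urine_output")
    if (!is.na(uo) && uo < 30) hit(condition, "high")
    if (!is.na(uo) && uo >= 30 && uo < 50) hit(condition, "moderate")
    if (identical(g("pe_proteinuria"), "plus1_or_300mg24h")) {
      hit(condition, "moderate")
    }
    pl <- g("pe_platelets")
    if (!is.na(pl) && pl < 50) hit(condition, "high")
    if (!is.na(pl) && pl >= 50 && pl <= 100) hit(condition, "moderate")
    tr <- g("pe_transaminases")
    if (!is.na(tr) && tr > 70) hit(condition, "high")
    cr <- g("pe_creatinine")
    if (!is.na(cr) && cr > 1.1) hit(condition, "high")
    if (!is.na(cr) && cr >= 0.8 && cr <= 1.1) hit(condition, "moderate")
    mg <- g("pe_mgso4_respiration")
    if (!is.na(mg) && mg < 12) hit(condition, "high")
    if (identical(g("pe_patellar_reflexes"), "depressed")) {
      hit(condition, "moderate")
    }
  } else if (condition == "sepsis") {
    ams <- g("sep_altered_mental_state")
    if (identical(ams, "current_exam")) hit(condition, "high")
    if (identical(ams, "history_only")) hit(condition, "moderate")
    rr <- g("respiratory_rate")
    if (!is.na(rr) && rr >= 25) hit(condition, "high")
    if (!is.na(rr) && rr >= 21 && rr < 25) hit(condition, "moderate")
    if (isTRUE(g("sep_needs_fio2_over_40"))) hit(condition, "high")
    sbp <- g("systolic_bp")
    if (!is.na(sbp) && sbp <= 90) hit(condition, "high")
    if (!is.na(sbp) && sbp > 90 && sbp <= 100) hit(condition, "moderate")
    hr <- g("pulse")
    if (!is.na(hr) && hr >= 130) hit(condition, "high")
    if (!is.na(hr) && hr >= 100 && hr < 130) hit(condition, "moderate")
    hu <- g("sep_hours_without_urine")
    if (!is.na(hu) && hu >= 18) hit(condition, "high")
    if (!is.na(hu) && hu >= 12 && hu < 18) hit(condition, "moderate")
    uo <- g("sep_urine_output_ml_kg_h")
    if (!is.na(uo) && uo < 0.5) hit(condition, "high")
    if (!is.na(uo) && uo >= 0.5 && uo <= 1) hit(condition, "moderate")
    te <- g("temperature")
    if (!is.na(te) && te > 39) hit(condition, "high")
    if (!is.na(te) && te < 36) hit(condition, "moderate")
    sk <- g("sep_skin")
    if (identical(sk, "mottled_cyanosis_rash")) hit(condition, "high")
    if (identical(sk, "wound_infection_signs")) hit(condition, "moderate")
  }
  if ("high" %in% tiers) "high" else if ("moderate" %in% tiers) "moderate"
  else "low"
}

# Truth-table oracle for the combined dichotomy.
oracle_combined <- function(ri_level, meows_total) {
  if (ri_level %in% c("moderate", "high")) return("moderate_or_high")
  if (!is.na(meows_total) && meows_total >= 3) return("moderate_or_high")
  "low"
}

# Closed-form Pearson chi-square for a 2x2 table.
oracle_chisq <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  n * (tp * tn - fp * fn)^2 /
    ((tp + fp) * (fn + tn) * (tp + fn) * (fp + tn))
}

# Katz log-interval oracle.
oracle_katz <- function(tp, fp, fn, tn, conf = 0.95) {
  rr <- (tp / (tp + fp)) / (fn / (fn + tn))
  se <- sqrt(1 / tp - 1 / (tp + fp) + 1 / fn - 1 / (fn + tn))
  z <- qnorm(1 - (1 - conf) / 2)
  c(rr = rr, lo = exp(log(rr) - z * se), hi = exp(log(rr) + z * se))
}

round_half_up_ <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
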