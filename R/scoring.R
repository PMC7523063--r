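#' Score one MEOWS parameter
#'
#' Maps measurements of a single physiologic parameter onto its 0--3
#' component score under a band table. Values are snapped to instrument
#' precision first (temperature 0.1 degC, all others integer), so printed
#' band endpoints are unambiguous. If a value falls in a gap between bands
#' of a user-supplied table, or inside overlapping bands, the table's gap
#' policy applies; the default policy scores the more severe (higher) of
#' the adjacent or containing bands.
#'
#' @param parameter One of `"temperature"`, `"systolic_bp"`,
#'   `"diastolic_bp"`, `"pulse"`, `"respiratory_rate"`, `"avpu"`,
#'   `"urine_output"`.
#' @param value Numeric vector of measurements (character vector of AVPU
#'   levels when `parameter = "avpu"`). `NA` values return `NA` scores.
#' @param bands A `meows_bands` table; defaults to the shipped chart.
#' @return Integer vector of component scores in 0--3.
#' @export
#' @examples
#' score_component("systolic_bp", c(100, 165, 80))
#' score_component("avpu", "Alert")
score_component <- function(parameter, value, bands = meows_bands()) {
  validate_bands(bands)
  if (length(parameter) != 1 || !parameter %in% meows_parameters()) {
    stop_meowsri(sprintf("Unknown MEOWS parameter '%s'.",
                         paste(parameter, collapse = ",")),
                 "meowsri_config_error")
  }
  if (parameter == "avpu") {
    value <- as.character(value)
    bad <- !is.na(value) & !value %in% avpu_levels
    if (any(bad)) {
      stop_meowsri(sprintf(
        "Invalid AVPU value(s): %s (must be one of %s).",
        paste(unique(value[bad]), collapse = ", "),
        paste(avpu_levels, collapse = "/")), "meowsri_validation_error")
    }
    return(as.integer(attr(bands, "avpu")[value]))
  }
  dom <- attr(bands, "domain")[[parameter]]
  v <- snap_to_precision(as.numeric(value), parameter)
  bad <- !is.na(v) & (v < dom[1] | v > dom[2])
  if (any(bad)) {
    stop_meowsri(sprintf(
      "%s value(s) outside admissible domain [%s, %s]: %s.",
      parameter, dom[1], dom[2],
      paste(unique(v[bad]), collapse = ", ")), "meowsri_validation_error")
  }
  b <- bands[bands$parameter == parameter, ]
  # integer comparisons at instrument precision avoid float boundary issues
  scale <- if (parameter == "temperature") 10 else 1
  vi <- round(v * scale)
  lo <- round(b$lower * scale)
  hi <- round(b$upper * scale)
  out <- rep(NA_integer_, length(vi))
  for (k in seq_along(vi)) {
    if (is.na(vi[k])) next
    inside <- vi[k] >= lo & vi[k] <= hi
    if (any(inside)) {
      out[k] <- as.integer(max(b$score[inside]))   # overlap -> more severe
    } else {
      below <- hi < vi[k]
      above <- lo > vi[k]
      adj <- c(
        if (any(below)) b$score[below][which.max(hi[below])],
        if (any(above)) b$score[above][which.min(lo[above])]
      )
      out[k] <- as.integer(max(adj))               # gap -> more severe adjacent
    }
  }
  out
}

#' Apply the MEOWS pulse rule
#'
#' The chart's footnote rule: when the pulse rate exceeds the systolic
#' blood pressure, the pulse component scores at least 2. Implemented as a
#' floor (`max(band_score, 2)`) so the rule can never lower a band score of
#' 3. When either input is missing the rule is skipped and the band score
#' returned unchanged.
#'
#' @param band_score Integer vector of pulse band scores (0--3).
#' @param pulse,systolic_bp Numeric vectors (beats/min, mmHg).
#' @return Integer vector of adjusted pulse scores.
#' @export
#' @examples
#' apply_pulse_rule(0, pulse = 110, systolic_bp = 100)  # -> 2
apply_pulse_rule <- function(band_score, pulse, systolic_bp) {
  fire <- !is.na(pulse) & !is.na(systolic_bp) & pulse > systolic_bp
  out <- as.integer(band_score)
  out[fire] <- pmax(out[fire], 2L)
  out
}

#' Classify a MEOWS total into its trigger category
#'
#' Track-and-trigger tiers: a total of 2 or less continues the current
#' plan; 3--5 calls for repeated observations and senior midwife review;
#' 6 or more escalates (coordinator/medical/anesthesia review, referral).
#'
#' @param total Non-negative integer vector of MEOWS totals (`NA` allowed).
#' @return Factor with levels `current_plan < review < escalate`.
#' @export
#' @examples
#' classify_trigger(c(0, 3, 7))
classify_trigger <- function(total) {
  if (any(!is.na(total) & total < 0)) {
    stop_meowsri("MEOWS totals must be non-negative.",
                 "meowsri_validation_error")
  }
  cat <- dplyr::case_when(
    is.na(total) ~ NA_character_,
    total <= 2 ~ "current_plan",
    total <= 5 ~ "review",
    TRUE ~ "escalate"
  )
  factor(cat, levels = c("current_plan", "review", "escalate"), ordered = TRUE)
}

#' Score a cohort's vital-sign observations
#'
#' Data-frame-first MEOWS scorer. Takes one row per observation with the
#' seven physiologic columns (`temperature`, `systolic_bp`, `diastolic_bp`,
#' `pulse`, `respiratory_rate`, `avpu`, `urine_output`, plus the optional
#' logical `urine_not_measured`), scores each parameter against the band
#' table, applies the pulse rule, and appends per-component scores, the
#' total over present components, the number of missing components, the
#' trigger category and a pulse-rule flag.
#'
#' Missing inputs never contribute to the total; an observation with all
#' seven inputs missing is unscorable and gets `NA` total and trigger (such
#' rows are excluded downstream by [triage()]). A urine output documented
#' as "not measured" scores 0 — it is a data-quality flag, not a missing
#' component.
#'
#' @param data Data frame of observations (extra columns are kept).
#' @param bands A `meows_bands` table.
#' @return The input as a tibble with columns `score_<parameter>` (7 of
#'   them), `meows_total`, `meows_n_missing`, `meows_trigger`,
#'   `pulse_rule_applied` appended.
#' @export
#' @examples
#' obs <- tibble::tibble(temperature = 37, systolic_bp = 115,
#'   diastolic_bp = 75, pulse = 80, respiratory_rate = 16,
#'   avpu = "Alert", urine_output = 60)
#' score_meows(obs)[, c("meows_total", "meows_trigger")]
score_meows <- function(data, bands = meows_bands()) {
  validate_bands(bands)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    stop_meowsri("Empty cohort: nothing to score.", "meowsri_validation_error")
  }
  params <- meows_parameters()
  for (p in setdiff(params, c("urine_output"))) {
    if (!p %in% names(data)) data[[p]] <- NA
  }
  if (!"urine_output" %in% names(data)) data$urine_output <- NA_real_
  unm <- if ("urine_not_measured" %in% names(data)) {
    !is.na(data$urine_not_measured) & data$urine_not_measured
  } else rep(FALSE, nrow(data))

  scores <- purrr::map(setNames(params, params), function(p) {
    if (p == "urine_output") {
      s <- score_component(p, data[[p]], bands)
      s[unm] <- 0L  # documented as not measured: flag, not absence
      s
    } else {
      score_component(p, data[[p]], bands)
    }
  })
  raw_pulse <- scores$pulse
  scores$pulse <- apply_pulse_rule(scores$pulse, data$pulse, data$systolic_bp)
  pulse_rule_applied <- !is.na(scores$pulse) & !is.na(raw_pulse) &
    scores$pulse != raw_pulse

  mat <- do.call(cbind, scores)
  n_missing <- rowSums(is.na(mat))
  total <- ifelse(n_missing == length(params), NA_integer_,
                  rowSums(mat, na.rm = TRUE))
  for (p in params) data[[paste0("score_", p)]] <- scores[[p]]
  data$meows_total <- as.integer(total)
  data$meows_n_missing <- as.integer(n_missing)
  data$meows_trigger <- classify_trigger(data$meows_total)
  data$pulse_rule_applied <- pulse_rule_applied
  data
}
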