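#' Build a 2x2 contingency table of triage decision vs morbidity
#'
#' Cross-tabulates the binary triage exposure (moderate/high vs low)
#' against the composite morbidity outcome. Cells follow the diagnostic
#' convention: `tp` = moderate/high and morbid, `fp` = moderate/high and
#' not morbid, `fn` = low and morbid, `tn` = low and not morbid.
#'
#' @param predicted Factor/character of `"moderate_or_high"`/`"low"`
#'   decisions, or a logical vector (`TRUE` = moderate/high).
#' @param outcome Logical vector of morbidity outcomes, same length.
#' @return An object of class `contingency_2x2`: a list with elements
#'   `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
#' @examples
#' contingency(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
contingency <- function(predicted, outcome) {
  if (length(predicted) != length(outcome)) {
    stop_meowsri("`predicted` and `outcome` must have the same length.",
                 "meowsri_validation_error")
  }
  if (length(predicted) == 0) {
    stop_meowsri("Cannot tabulate an empty cohort.",
                 "meowsri_validation_error")
  }
  if (!is.logical(predicted)) {
    predicted <- as.character(predicted) == "moderate_or_high"
  }
  outcome <- as.logical(outcome)
  keep <- !is.na(predicted) & !is.na(outcome)
  p <- predicted[keep]
  o <- outcome[keep]
  as_contingency(tp = sum(p & o), fp = sum(p & !o),
                 fn = sum(!p & o), tn = sum(!p & !o))
}

#' @rdname contingency
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @export
as_contingency <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop_meowsri("Contingency cells must be non-negative counts.",
                 "meowsri_validation_error")
  }
  if (sum(cells) == 0) {
    stop_meowsri("Contingency table must have at least one record.",
                 "meowsri_validation_error")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = sum(cells)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("moderate_or_high", "low"),
                              c("morbid", "not_morbid")))
  cat("2x2 triage-by-morbidity table (n =", x$n, ")\n")
  print(m)
  invisible(x)
}

#' Diagnostic-test proportions from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values `tp/(tp+fp)` and `tn/(tn+fn)`, and accuracy
#' `(tp+tn)/n`. Any statistic with a zero denominator is reported as `NA`;
#' the others are still computed.
#'
#' @param t A `contingency_2x2` object (see [contingency()]).
#' @return One-row tibble with columns `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy` (proportions in `[0, 1]`) and `n`.
#' @export
#' @examples
#' diagnostics(as_contingency(13, 23, 32, 331))
diagnostics <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    sensitivity = safe_div(t$tp, t$tp + t$fn),
    specificity = safe_div(t$tn, t$tn + t$fp),
    ppv = safe_div(t$tp, t$tp + t$fp),
    npv = safe_div(t$tn, t$tn + t$fn),
    accuracy = safe_div(t$tp + t$tn, t$n),
    n = t$n
  )
}

#' Relative risk with a Katz log-scale confidence interval
#'
#' The relative risk of morbidity in the moderate/high group versus the
#' low group, `[tp/(tp+fp)] / [fn/(fn+tn)]`, with the Katz interval
#' `exp(log(rr) +/- z * sqrt(1/tp - 1/(tp+fp) + 1/fn - 1/(fn+tn)))`. When
#' any cell is zero the Haldane-Anscombe continuity correction (0.5 added
#' to every cell) is applied and flagged; a zero exposed or unexposed
#' margin leaves the estimate undefined (`NA`).
#'
#' @param t A `contingency_2x2` object.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `conf_low`, `conf_high`,
#'   `conf_level`, `method`, `continuity_corrected`.
#' @export
#' @examples
#' relative_risk(as_contingency(13, 23, 32, 331))
relative_risk <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  check_prob(conf_level, "conf_level")
  tp <- t$tp; fp <- t$fp; fn <- t$fn; tn <- t$tn
  if (tp + fp == 0 || fn + tn == 0) {
    warn("Zero exposed or unexposed margin: relative risk undefined.")
    return(tibble::tibble(estimate = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, conf_level = conf_level,
                          method = "katz", continuity_corrected = FALSE))
  }
  corrected <- any(c(tp, fp, fn, tn) == 0)
  if (corrected) {
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  rr <- (tp / (tp + fp)) / (fn / (fn + tn))
  se <- sqrt(1 / tp - 1 / (tp + fp) + 1 / fn - 1 / (fn + tn))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    estimate = rr,
    conf_low = exp(log(rr) - z * se),
    conf_high = exp(log(rr) + z * se),
    conf_level = conf_level,
    method = "katz",
    continuity_corrected = corrected
  )
}

#' Pearson chi-square test of association on a 2x2 table
#'
#' Tests the association between the triage dichotomy and morbidity.
#' Continuity (Yates) correction is off by default; enable it with
#' `correct = TRUE`. A zero row or column margin leaves the statistic
#' undefined.
#'
#' @param t A `contingency_2x2` object.
#' @param correct Apply the Yates continuity correction?
#' @return One-row tibble: `statistic`, `df`, `p_value`, `correct`.
#' @export
#' @examples
#' chi_square_2x2(as_contingency(13, 23, 32, 331))
chi_square_2x2 <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  m <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warn("Zero margin: chi-square statistic undefined.")
    return(tibble::tibble(statistic = NA_real_, df = 1L,
                          p_value = NA_real_, correct = correct))
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic), df = 1L,
                 p_value = unname(ct$p.value), correct = correct)
}

#' Evaluate a cohort end to end
#'
#' Runs [triage()] on a cohort, pairs each classifiable decision with the
#' composite morbidity outcome (the logical OR of `outcome_pph`,
#' `outcome_infection` and `outcome_preeclampsia`, or a `morbidity`
#' column if present), excludes records lacking either the predictor or
#' the outcome (listwise, with a logged count), and computes the 2x2
#' table, the diagnostic proportions, the Katz relative risk and the
#' chi-square association test.
#'
#' @param data Cohort data frame.
#' @param bands MEOWS band table.
#' @param rule Combination rule passed to [triage()].
#' @param conf_level Confidence level for the relative-risk interval.
#' @param correct Yates correction for the chi-square test.
#' @return An object of class `meows_evaluation`: a list with elements
#'   `contingency` (`contingency_2x2`), `diagnostics`, `relative_risk`,
#'   `chi_square` (tibbles), `n_total`, `n_analyzable`, `n_excluded`,
#'   `rule`. Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 200, seed = 7))
#' evaluate_cohort(cohort)
evaluate_cohort <- function(data, bands = meows_bands(),
                            rule = "disjunction", conf_level = 0.95,
                            correct = FALSE) {
  decisions <- triage(data, bands, rule)
  morb <- cohort_morbidity(decisions)
  usable <- !is.na(decisions$combined_level) & !is.na(morb)
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    inform(sprintf(
      "evaluate_cohort: excluding %d of %d record(s) without complete predictor and outcome data.",
      n_excluded, nrow(decisions)))
  }
  tab <- contingency(decisions$combined_level[usable], morb[usable])
  structure(list(
    contingency = tab,
    diagnostics = diagnostics(tab),
    relative_risk = relative_risk(tab, conf_level),
    chi_square = chi_square_2x2(tab, correct),
    n_total = nrow(decisions),
    n_analyzable = tab$n,
    n_excluded = n_excluded,
    rule = rule
  ), class = "meows_evaluation")
}

# Composite morbidity: OR of the three outcome components, or an explicit
# morbidity column.
cohort_morbidity <- function(data) {
  if ("morbidity" %in% names(data)) return(as.logical(data$morbidity))
  comp <- intersect(c("outcome_pph", "outcome_infection",
                      "outcome_preeclampsia"), names(data))
  if (length(comp) == 0) {
    stop_meowsri(
      "Cohort has neither a `morbidity` column nor outcome components.",
      "meowsri_validation_error")
  }
  m <- as.data.frame(data[, comp])
  all_na <- rowSums(!is.na(m)) == 0
  out <- rowSums(m, na.rm = TRUE) > 0
  out[all_na] <- NA
  out
}

#' @export
print.meows_evaluation <- function(x, ...) {
  cat(sprintf("RI & MEOWS evaluation (%s rule): %d records, %d analyzable, %d excluded\n",
              x$rule, x$n_total, x$n_analyzable, x$n_excluded))
  print(x$contingency)
  d <- x$diagnostics
  pct <- function(v) sprintf("%.1f%%", round_half_up(100 * v, 1))
  cat(sprintf(
    "sensitivity %s  specificity %s  PPV %s  NPV %s  accuracy %s\n",
    pct(d$sensitivity), pct(d$specificity), pct(d$ppv), pct(d$npv),
    pct(d$accuracy)))
  rr <- x$relative_risk
  cat(sprintf("relative risk %.1f (%d%% CI %.1f-%.1f, Katz)\n",
              round_half_up(rr$estimate, 1), round(100 * rr$conf_level),
              round_half_up(rr$conf_low, 1), round_half_up(rr$conf_high, 1)))
  cs <- x$chi_square
  cat(sprintf("chi-square %.2f (df 1), p %s\n", cs$statistic,
              format.pval(cs$p_value, digits = 3, eps = 1e-4)))
  invisible(x)
}

#' Audit form completeness of a cohort
#'
#' The feasibility measure: classifies each record's bedside form as
#' `completed` (every required field documented), `empty` (none
#' documented) or `partial` (anything in between), and reports counts and
#' fractions. A urine output marked "not measured" counts as documented.
#'
#' @param data Cohort data frame.
#' @param required_fields Character vector of required column names;
#'   defaults to the bedside form fields (demographics age/gravida/parity
#'   plus the seven vital-sign fields).
#' @param by_record Return the per-record status column instead of the
#'   summary?
#' @return One-row tibble `n_total`, `n_completed`, `n_partial`,
#'   `n_empty`, `frac_completed`, `frac_partial`, `frac_empty` (class
#'   `completeness_report`, with the field list as attribute), or a factor
#'   of per-record statuses when `by_record = TRUE`.
#' @export
#' @examples
#' completeness_audit(study_replica_fixture())
completeness_audit <- function(data, required_fields = form_fields(),
                               by_record = FALSE) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    stop_meowsri("Empty cohort: nothing to audit.",
                 "meowsri_validation_error")
  }
  if (length(required_fields) == 0) {
    stop_meowsri("`required_fields` must name at least one column.",
                 "meowsri_validation_error")
  }
  present <- sapply(required_fields, function(f) {
    if (!f %in% names(data)) return(rep(FALSE, nrow(data)))
    p <- !is.na(data[[f]])
    if (f == "urine_output" && "urine_not_measured" %in% names(data)) {
      p <- p | (!is.na(data$urine_not_measured) & data$urine_not_measured)
    }
    p
  })
  present <- matrix(present, nrow = nrow(data))
  n_present <- rowSums(present)
  status <- factor(
    dplyr::case_when(
      n_present == length(required_fields) ~ "completed",
      n_present == 0 ~ "empty",
      TRUE ~ "partial"
    ), levels = c("completed", "partial", "empty"))
  if (by_record) return(status)
  counts <- table(status)
  out <- tibble::tibble(
    n_total = nrow(data),
    n_completed = as.integer(counts["completed"]),
    n_partial = as.integer(counts["partial"]),
    n_empty = as.integer(counts["empty"]),
    frac_completed = as.integer(counts["completed"]) / nrow(data),
    frac_partial = as.integer(counts["partial"]) / nrow(data),
    frac_empty = as.integer(counts["empty"]) / nrow(data)
  )
  attr(out, "required_fields") <- required_fields
  class(out) <- c("completeness_report", class(out))
  out
}

#' Bedside-form fields used by the completeness audit
#'
#' @return Character vector of the default required columns.
#' @export
form_fields <- function() {
  c("age", "gravida", "parity", "temperature", "systolic_bp",
    "diastolic_bp", "pulse", "respiratory_rate", "avpu", "urine_output")
}

#' Summarise a Likert question by its most favourable categories
#'
#' Computes, per question, the fraction of responses in the `top_k` most
#' favourable categories (e.g. "easy or very easy"). Categories must be
#' ordered from least to most favourable within each question.
#'
#' @param counts Tibble with columns `question`, `response` and `count`,
#'   responses in ascending favourability order within each question.
#' @param top_k Number of most-favourable categories to pool (default 2).
#' @return Tibble with columns `question`, `n`, `top_k`, `proportion`.
#' @export
#' @examples
#' likert_summary(staff_experience_counts())
likert_summary <- function(counts, top_k = 2) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("question", "response", "count") %in% names(counts)))
  if (any(counts$count < 0)) {
    stop_meowsri("Likert counts must be non-negative.",
                 "meowsri_validation_error")
  }
  counts |>
    dplyr::group_by(.data$question) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) {
        stop_meowsri("Each Likert question needs at least 2 categories.",
                     "meowsri_validation_error")
      }
      if (top_k >= nrow(g)) {
        stop_meowsri("`top_k` must be smaller than the number of categories.",
                     "meowsri_validation_error")
      }
      total <- sum(g$count)
      if (total == 0) {
        stop_meowsri("Likert question has zero total responses.",
                     "meowsri_validation_error")
      }
      top <- sum(utils::tail(g$count, top_k))
      tibble::tibble(n = total, top_k = top_k, proportion = top / total)
    }) |>
    dplyr::ungroup()
}

#' Staff-experience Likert responses
#'
#' The four staff-experience survey questions with their response counts,
#' in ascending favourability order, as collected in the instrument's
#' district-hospital implementation: ease of use within the patient file
#' (n = 25), willingness to use the tool regularly (n = 22), perceived
#' improvement of patient-safety awareness (n = 23), and perceived
#' reduction of delay in recognising critically ill patients (n = 22).
#'
#' @return Tibble with columns `question`, `response`, `count`.
#' @export
#' @examples
#' likert_summary(staff_experience_counts(), top_k = 2)
staff_experience_counts <- function() {
  tibble::tribble(
    ~question, ~response, ~count,
    "ease_of_use", "very_difficult", 0,
    "ease_of_use", "difficult", 2,
    "ease_of_use", "easy", 16,
    "ease_of_use", "very_easy", 7,
    "willingness", "very_resistant", 0,
    "willingness", "resistant", 2,
    "willingness", "willing", 9,
    "willingness", "very_willing", 11,
    "safety_awareness", "not_at_all", 0,
    "safety_awareness", "somewhat_significant", 2,
    "safety_awareness", "significant", 9,
    "safety_awareness", "very_significant", 12,
    "delay_reduction", "not_at_all", 0,
    "delay_reduction", "somewhat_significant", 3,
    "delay_reduction", "significant", 4,
    "delay_reduction", "very_significant", 15
  )
}
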