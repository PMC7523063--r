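#' Triage a cohort into the low vs moderate/high dichotomy
#'
#' Runs the MEOWS scorer and the RI classifiers on a cohort's admission
#' observations and combines them into the binary exposure used by the
#' diagnostic evaluation. Under the default `"disjunction"` rule a record
#' is `moderate_or_high` when its RI overall level is moderate or high
#' *or* its MEOWS total reaches the review tier (total >= 3); otherwise it
#' is `low`. The alternative rules `"ri_only"` and `"meows_only"` use a
#' single instrument, for sensitivity analyses of the combination.
#'
#' Records in which both instruments are undocumented (no scoreable vital
#' sign and no RI input) are unclassifiable: `combined_level` is `NA` and
#' `excluded_reason` says why, mirroring the exclusion of incomplete
#' bedside forms from an evaluation.
#'
#' @param data Cohort data frame (cohort-dialect columns).
#' @param bands MEOWS band table.
#' @param rule Combination rule: `"disjunction"` (default), `"ri_only"`,
#'   or `"meows_only"`.
#' @return The input as a tibble with the [score_meows()] and
#'   [classify_risk()] columns plus `combined_level` (factor
#'   `low < moderate_or_high`, `NA` when unclassifiable), `basis`
#'   (semicolon-joined sources that fired: RI conditions at moderate+ and/or
#'   `"meows"`), and `excluded_reason`.
#' @seealso [evaluate_cohort()]
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 1))
#' dplyr::count(triage(cohort), combined_level)
triage <- function(data, bands = meows_bands(),
                   rule = c("disjunction", "ri_only", "meows_only")) {
  rule <- match.arg(rule)
  scored <- score_meows(data, bands)
  scored <- classify_risk(scored)

  ri_fires <- !is.na(scored$ri_overall) & scored$ri_overall >= "moderate"
  meows_fires <- !is.na(scored$meows_total) & scored$meows_total >= 3
  meows_known <- !is.na(scored$meows_total)
  ri_known <- scored$ri_available

  positive <- switch(rule,
    disjunction = ri_fires | meows_fires,
    ri_only = ri_fires,
    meows_only = meows_fires
  )
  unclassifiable <- switch(rule,
    disjunction = !meows_known & !ri_known,
    ri_only = !ri_known,
    meows_only = !meows_known
  )

  basis <- purrr::map_chr(seq_len(nrow(scored)), function(i) {
    src <- character()
    if (rule != "meows_only" && ri_fires[i]) {
      for (cond in c("hemorrhage", "preeclampsia", "sepsis")) {
        lvl <- scored[[paste0("ri_", cond)]][i]
        if (!is.na(lvl) && lvl >= "moderate") src <- c(src, paste0("ri_", cond))
      }
    }
    if (rule != "ri_only" && meows_fires[i]) src <- c(src, "meows")
    paste(src, collapse = ";")
  })

  scored$combined_level <- factor(
    ifelse(unclassifiable, NA_character_,
           ifelse(positive, "moderate_or_high", "low")),
    levels = c("low", "moderate_or_high"))
  scored$basis <- ifelse(unclassifiable, NA_character_, basis)
  scored$excluded_reason <- ifelse(
    unclassifiable, "no documented MEOWS observation or RI input",
    NA_character_)
  n_excl <- sum(unclassifiable)
  if (n_excl > 0) {
    inform(sprintf("triage: %d of %d record(s) unclassifiable (%s).",
                   n_excl, nrow(scored), "no MEOWS or RI data"))
  }
  scored
}
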