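#' Tidy a cohort evaluation
#'
#' One row per reported statistic of a [evaluate_cohort()] result:
#' the diagnostic proportions, the relative risk with its Katz interval,
#' and the chi-square association test.
#'
#' @param x A `meows_evaluation` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
tidy.meows_evaluation <- function(x, ...) {
  d <- x$diagnostics
  props <- tibble::tibble(
    term = c("sensitivity", "specificity", "ppv", "npv", "accuracy"),
    estimate = c(d$sensitivity, d$specificity, d$ppv, d$npv, d$accuracy),
    conf_low = NA_real_, conf_high = NA_real_, p_value = NA_real_
  )
  rr <- tibble::tibble(
    term = "relative_risk", estimate = x$relative_risk$estimate,
    conf_low = x$relative_risk$conf_low,
    conf_high = x$relative_risk$conf_high, p_value = NA_real_
  )
  cs <- tibble::tibble(
    term = "chi_square", estimate = x$chi_square$statistic,
    conf_low = NA_real_, conf_high = NA_real_,
    p_value = x$chi_square$p_value
  )
  dplyr::bind_rows(props, rr, cs)
}

#' Glance at a cohort evaluation
#'
#' @param x A `meows_evaluation` object.
#' @param ... Unused.
#' @return One-row tibble with the counts, cells and headline statistics.
#' @export
glance.meows_evaluation <- function(x, ...) {
  t <- x$contingency
  tibble::tibble(
    n_total = x$n_total, n_analyzable = x$n_analyzable,
    n_excluded = x$n_excluded,
    tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn,
    sensitivity = x$diagnostics$sensitivity,
    specificity = x$diagnostics$specificity,
    ppv = x$diagnostics$ppv, npv = x$diagnostics$npv,
    accuracy = x$diagnostics$accuracy,
    relative_risk = x$relative_risk$estimate,
    rr_conf_low = x$relative_risk$conf_low,
    rr_conf_high = x$relative_risk$conf_high,
    chi_square = x$chi_square$statistic,
    p_value = x$chi_square$p_value,
    rule = x$rule
  )
}

#' Plot a cohort evaluation
#'
#' Dot plot of the diagnostic proportions plus the relative risk with its
#' confidence interval on a free scale.
#'
#' @param object A `meows_evaluation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meows_evaluation <- function(object, ...) {
  td <- tidy(object)
  td$panel <- ifelse(td$term == "relative_risk", "relative risk",
                     ifelse(td$term == "chi_square", "association",
                            "proportion"))
  td <- td[td$term != "chi_square", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.15, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "RI & MEOWS diagnostic performance",
                  subtitle = sprintf("n = %d analyzable records",
                                     object$n_analyzable)) +
    ggplot2::theme_minimal()
}

#' Plot the MEOWS band table
#'
#' Horizontal bar chart of the numeric score bands, coloured by component
#' score, one row per parameter.
#'
#' @param bands A `meows_bands` table.
#' @return A ggplot object.
#' @export
plot_score_bands <- function(bands = meows_bands()) {
  validate_bands(bands)
  b <- tibble::as_tibble(bands)
  b$score <- factor(b$score, levels = 0:3)
  ggplot2::ggplot(b, ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                  ymin = 0, ymax = 1,
                                  fill = .data$score)) +
    ggplot2::geom_rect(colour = "white") +
    ggplot2::facet_wrap(~parameter, scales = "free_x", ncol = 2) +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", name = "score") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("MEOWS score bands (%s)",
                                  attr(bands, "version"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a completeness report
#'
#' @param report A `completeness_report` from [completeness_audit()].
#' @return A ggplot object.
#' @export
plot_completeness <- function(report) {
  stopifnot(inherits(report, "completeness_report"))
  df <- tibble::tibble(
    status = factor(c("completed", "partial", "empty"),
                    levels = c("completed", "partial", "empty")),
    fraction = c(report$frac_completed, report$frac_partial,
                 report$frac_empty)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", round_half_up(100 * .data$fraction, 1))),
      vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "share of forms",
                  title = "Bedside-form completeness",
                  subtitle = sprintf("n = %d forms", report$n_total)) +
    ggplot2::theme_minimal()
}
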