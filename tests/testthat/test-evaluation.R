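study_table <- function() as_contingency(13, 23, 32, 331)

test_that("contingency cross-tabulates decisions against morbidity", {
  t <- contingency(c(TRUE, TRUE, TRUE, TRUE, TRUE),
                   c(TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 5, fp = 0, fn = 0, tn = 0))
  expect_error(contingency(logical(0), logical(0)),
               class = "meowsri_validation_error")
  expect_error(contingency(c(TRUE, FALSE), TRUE),
               class = "meowsri_validation_error")
  # factor decisions, study margins
  dec <- c(rep("moderate_or_high", 36), rep("low", 363))
  out <- c(rep(TRUE, 13), rep(FALSE, 23), rep(TRUE, 32), rep(FALSE, 331))
  t2 <- contingency(factor(dec), out)
  expect_equal(unlist(t2[c("tp", "fp", "fn", "tn")]),
               c(tp = 13, fp = 23, fn = 32, tn = 331))
})

test_that("diagnostic proportions match hand-computed study values", {
  d <- diagnostics(study_table())
  expect_equal(round_half_up_(100 * d$sensitivity), 28.9)
  expect_equal(round_half_up_(100 * d$specificity), 93.5)
  expect_equal(round_half_up_(100 * d$ppv), 36.1)
  expect_equal(round_half_up_(100 * d$accuracy), 86.2)
  expect_equal(d$npv, 331 / 363, tolerance = 1e-12)
  d2 <- diagnostics(as_contingency(5, 0, 0, 5))
  expect_true(all(unlist(d2[1:5]) == 1))
})

test_that("diagnostics agree with a count-and-divide oracle on random tables", {
  withr::local_seed(5)
  for (rep in 1:50) {
    cells <- rbinom(4, 20, 0.5)
    if (sum(cells) == 0) next
    t <- as_contingency(cells[1], cells[2], cells[3], cells[4])
    # oracle: enumerate individual records and count
    rec_pred <- c(rep(TRUE, cells[1] + cells[2]),
                  rep(FALSE, cells[3] + cells[4]))
    rec_out <- c(rep(TRUE, cells[1]), rep(FALSE, cells[2]),
                 rep(TRUE, cells[3]), rep(FALSE, cells[4]))
    d <- diagnostics(t)
    se <- sum(rec_pred & rec_out) / sum(rec_out)
    sp <- sum(!rec_pred & !rec_out) / sum(!rec_out)
    if (sum(rec_out) > 0) expect_equal(d$sensitivity, se)
    if (sum(!rec_out) > 0) expect_equal(d$specificity, sp)
    expect_equal(d$accuracy, mean(rec_pred == rec_out))
  }
})

test_that("zero denominators leave single statistics undefined", {
  d <- diagnostics(as_contingency(0, 5, 0, 5))
  expect_true(is.na(d$sensitivity))  # no morbid records
  expect_false(is.na(d$specificity))
  expect_false(is.na(d$accuracy))
})

test_that("relative risk and Katz interval reproduce the study estimate", {
  rr <- relative_risk(study_table())
  expect_equal(round_half_up_(rr$estimate), 4.1)
  expect_equal(round_half_up_(rr$conf_low), 2.4)
  expect_equal(round_half_up_(rr$conf_high), 7.1)
  k <- oracle_katz(13, 23, 32, 331)
  expect_equal(rr$estimate, unname(k["rr"]), tolerance = 1e-12)
  expect_equal(rr$conf_low, unname(k["lo"]), tolerance = 1e-12)
  expect_equal(rr$conf_high, unname(k["hi"]), tolerance = 1e-12)
})

test_that("relative risk structural properties hold", {
  expect_equal(relative_risk(as_contingency(10, 90, 10, 90))$estimate, 1)
  withr::local_seed(6)
  for (rep in 1:30) {
    cells <- rbinom(4, 30, 0.5) + 1
    rr <- relative_risk(as_contingency(cells[1], cells[2], cells[3],
                                       cells[4]))
    expect_true(rr$conf_low <= rr$estimate && rr$estimate <= rr$conf_high)
  }
  # zero cell: continuity correction flagged
  rr0 <- relative_risk(as_contingency(0, 10, 5, 10))
  expect_true(rr0$continuity_corrected)
  expect_true(is.finite(rr0$estimate))
  # zero exposed margin: undefined
  expect_warning(rrx <- relative_risk(as_contingency(0, 0, 5, 10)))
  expect_true(is.na(rrx$estimate))
})

test_that("bootstrap of the study table brackets the Katz interval", {
  withr::local_seed(7)
  b <- 4000
  exp_risk <- rbinom(b, 36, 13 / 36) / 36
  unexp_risk <- rbinom(b, 363, 32 / 363) / 363
  rrs <- exp_risk / unexp_risk
  q <- stats::quantile(rrs, c(0.025, 0.975))
  rr <- relative_risk(study_table())
  # resampling interval and Katz interval agree to ~15%
  expect_equal(unname(q[1]), rr$conf_low, tolerance = 0.15)
  expect_equal(unname(q[2]), rr$conf_high, tolerance = 0.15)
})

test_that("Katz interval attains close to nominal coverage", {
  withr::local_seed(8)
  n_sim <- 2000
  n1 <- 150; n0 <- 450; p1 <- 0.3; p0 <- 0.1
  true_rr <- p1 / p0
  a <- rbinom(n_sim, n1, p1)
  c_ <- rbinom(n_sim, n0, p0)
  covered <- vapply(seq_len(n_sim), function(i) {
    rr <- relative_risk(as_contingency(a[i], n1 - a[i], c_[i], n0 - c_[i]))
    !is.na(rr$conf_low) && rr$conf_low <= true_rr && true_rr <= rr$conf_high
  }, logical(1))
  # Monte-Carlo SE of a 95% coverage estimate at 2000 reps is ~0.5%
  expect_equal(mean(covered), 0.95, tolerance = 0.02)
})

test_that("chi-square matches the closed-form oracle and the study p-value", {
  cs <- chi_square_2x2(study_table())
  expect_equal(cs$statistic, oracle_chisq(13, 23, 32, 331),
               tolerance = 1e-12)
  expect_lt(cs$p_value, 0.0001)
  flat <- chi_square_2x2(as_contingency(25, 25, 25, 25))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_warning(bad <- chi_square_2x2(as_contingency(0, 0, 5, 10)))
  expect_true(is.na(bad$statistic))
})

test_that("statistics are invariant under scaling all four cells", {
  t1 <- study_table()
  t5 <- as_contingency(5 * 13, 5 * 23, 5 * 32, 5 * 331)
  expect_equal(diagnostics(t1)[1:5], diagnostics(t5)[1:5])
  expect_equal(relative_risk(t1)$estimate, relative_risk(t5)$estimate)
  expect_equal(chi_square_2x2(t5)$statistic,
               5 * chi_square_2x2(t1)$statistic, tolerance = 1e-9)
})

test_that("accuracy equals the prevalence-weighted identity", {
  withr::local_seed(9)
  for (rep in 1:30) {
    cells <- rbinom(4, 40, 0.5) + 1
    t <- as_contingency(cells[1], cells[2], cells[3], cells[4])
    d <- diagnostics(t)
    prev <- (t$tp + t$fn) / t$n
    expect_equal(d$accuracy,
                 d$sensitivity * prev + d$specificity * (1 - prev),
                 tolerance = 1e-12)
  }
})

test_that("completeness audit reproduces the fixture margins", {
  aud <- completeness_audit(study_replica_fixture())
  expect_equal(aud$n_total, 478)
  expect_equal(aud$n_completed, 363)
  expect_equal(aud$n_partial, 79)
  expect_equal(aud$n_empty, 36)
  expect_equal(round_half_up_(100 * aud$frac_completed), 75.9)
  expect_equal(round_half_up_(100 * aud$frac_partial), 16.5)
  expect_equal(round_half_up_(100 * aud$frac_empty), 7.5)
  expect_equal(aud$frac_completed + aud$frac_partial + aud$frac_empty, 1)
})

test_that("completeness audit agrees with a field-counting oracle", {
  withr::local_seed(10)
  co <- generate_cohort(cohort_config(n = 300, seed = 10))
  fields <- form_fields()
  statuses <- completeness_audit(co, by_record = TRUE)
  for (i in seq_len(nrow(co))) {
    present <- sum(vapply(fields, function(f) {
      p <- !is.na(co[[f]][i])
      if (f == "urine_output") p <- p || isTRUE(co$urine_not_measured[i])
      p
    }, logical(1)))
    want <- if (present == length(fields)) "completed"
            else if (present == 0) "empty" else "partial"
    expect_identical(as.character(statuses[i]), want)
  }
  # all-complete cohort
  full <- completeness_audit(co[co$form_status == "completed", ])
  expect_equal(full$frac_completed, 1)
  expect_equal(full$frac_partial + full$frac_empty, 0)
})

test_that("Likert top-2 summaries reproduce the survey percentages", {
  s <- likert_summary(staff_experience_counts(), top_k = 2)
  prop <- setNames(s$proportion, s$question)
  expect_equal(round_half_up_(100 * prop[["ease_of_use"]]), 92.0)
  expect_equal(round_half_up_(100 * prop[["willingness"]]), 90.9)
  expect_equal(round_half_up_(100 * prop[["safety_awareness"]]), 91.3)
  expect_equal(round_half_up_(100 * prop[["delay_reduction"]]), 86.4)
  # degenerate: everything in one category, top 1
  one <- tibble::tibble(question = "q", response = c("a", "b"),
                        count = c(0, 7))
  expect_equal(likert_summary(one, top_k = 1)$proportion, 1)
  expect_error(likert_summary(one, top_k = 2),
               class = "meowsri_validation_error")
})

test_that("evaluate_cohort excludes records listwise and reports counts", {
  fx <- study_replica_fixture()
  ev <- suppressMessages(evaluate_cohort(fx))
  expect_equal(ev$n_total, 478)
  expect_equal(ev$n_analyzable, 399)
  expect_equal(ev$n_excluded, 79)
  g <- glance(ev)
  expect_equal(c(g$tp, g$fp, g$fn, g$tn), c(13, 23, 32, 331))
  td <- tidy(ev)
  expect_true(all(c("sensitivity", "relative_risk", "chi_square") %in%
                    td$term))
  expect_equal(td$estimate[td$term == "relative_risk"],
               relative_risk(study_table())$estimate)
})

test_that("plots build without error", {
  ev <- suppressMessages(evaluate_cohort(study_replica_fixture()))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_score_bands(), "ggplot")
  expect_s3_class(plot_completeness(completeness_audit(
    study_replica_fixture())), "ggplot")
})
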