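---
title: "Methods: the RI & MEOWS triage instrument and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the RI & MEOWS triage instrument and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meowsri)
library(dplyr)
```

## The instrument

`meowsri` implements a combined bedside instrument for parturients in
low-resource obstetric units, built from two parts that share one admission
observation:

* a **Risk Identification (RI) checklist** grading the risk of hemorrhage,
  preeclampsia/eclampsia and sepsis as *low*, *moderate* or *high* from
  admission criteria (history flags, symptoms, laboratory values, vital
  signs), each condition under a max rule — one high-tier criterion makes
  the condition high risk, otherwise one moderate-tier criterion makes it
  moderate;
* a **Modified Early Obstetric Warning Score (MEOWS)**, a track-and-trigger
  score assigning 0–3 points to each of seven physiologic parameters
  (temperature, systolic and diastolic blood pressure, pulse, respiratory
  rate, AVPU consciousness, hourly urine output). The total maps to action
  tiers: ≤ 2 continue the current plan, 3–5 repeat observations with senior
  midwife review, ≥ 6 escalate (coordinator, medical and anesthesia review,
  referral).

For evaluation the two instruments are dichotomised per record: a record is
*moderate/high* when its RI overall level is at least moderate **or** its
MEOWS total reaches the review tier (≥ 3), and *low* otherwise. This
disjunction is a design choice of the package — the dichotomy itself is
standard, its construction is not printed anywhere — and `triage()` exposes
`ri_only` and `meows_only` rules so the evaluation can be rerun under the
alternatives.

## The band table and its repairs

Bedside charts of this family are printed with the 0-point column in the
middle and severity growing outward. Printed charts of the instrument are
ambiguous in places, so the shipped table (`meows_bands()`, version tag
`rw-meows-v1`) is a fully enumerated, documented alignment rather than a
verbatim transcription:

* the printed systolic chart leaves **80 mmHg unassigned** (bands 71–79 and
  81–89) and the pulse chart assigns **40 bpm twice** (≤ 40 and 40–50). Both
  are resolved to the **more severe adjacent band** — clinically
  conservative and deterministic. The same policy is applied at scoring
  time to any user-supplied table with residual gaps or overlaps.
* printed interval endpoints are treated as closed, and values are snapped
  to instrument precision before comparison (temperature 0.1 °C, all other
  parameters integer), which removes floating-point boundary ambiguity.
* a urine output documented as **"not measured" scores 0** but is retained
  as a data-quality flag (`urine_not_measured`): an absent measurement
  should not inflate the total, yet the audit must still see the field as
  documented.
* the footnote rule "pulse rate higher than the systolic blood pressure →
  score 2 for pulse" is implemented as a **floor** (`max(band, 2)`), never
  an override, so it cannot lower a tachycardia already scoring 3.

The table is configuration, not code: `write_bands()`/`read_bands()`
round-trip it through YAML, so alternative alignments of the ambiguous
temperature, diastolic, respiratory-rate and urine rows can be loaded
without touching the package.

Missing components never contribute to the total; `score_meows()` records
`meows_n_missing` and scores over the present components. An observation
with all seven inputs missing is unscorable: in the vectorised data-frame
surface this is reported as an `NA` total rather than an error, so one
blank form cannot abort a cohort run; `triage()` subsequently excludes such
records with a reason. Whether the review band applied at admission only or
at every observation is not stated for the original deployment; the package
scores every observation it is given.

## The RI criteria catalogue and its repairs

`ri_criteria()` enumerates every checklist cell with a stable identifier.
Three families of print defects in the source chart needed documented
repairs:

1. **Duplicated criteria** (nausea/vomiting, abdominal pain, chest pain,
   ASAT/ALAT > 70 appear in more than one tier): assigned the **highest
   printed tier**, conservative and deterministic.
2. **Numeric gaps between tiers** (creatinine 0.8–0.9 and 1.1–1.2, sepsis
   systolic exactly 90, respiratory rate exactly 25, heart rate exactly
   130; preeclampsia urine output between 15 and 30 mL/h after unit
   normalisation): resolved to the **more severe tier**, consistent with
   the band-table gap policy.
3. **Garbled preeclampsia CVS columns** (the same DBP range printed under
   two tiers, a high heart rate printed under low risk): realigned to
   standard obstetric severity thresholds — DBP ≥ 110 high, 90–109
   moderate; heart rate ≥ 130 high, 111–129 moderate; systolic as printed
   (≥ 160 high, 140–159 moderate).

Two further reading decisions: the sepsis *screening* risk factors
(diabetes/comorbidity, recent invasive procedure, prolonged rupture of
membranes, bleeding/offensive discharge) are printed identically under all
three columns — they are recorded as flags (`ri_flags`) that prompt
assessment but never raise the level by themselves; and the labor/postpartum
hemorrhage re-evaluation items (prolonged second stage, prolonged oxytocin,
magnesium sulfate) are printed without a tier of their own and map to the
moderate tier, the least severe actionable one. The hematocrit < 30 /
transfusion-refusal / other-risk item is one conjunctive flag supplied by
the user, not three separate fields, because the chart binds them with an
"AND". The severe-oliguria cell is a 2-hour volume while the other tiers
are hourly; `normalize_urine_output()` converts timed collections, and the
cohort dialect stores hourly rates throughout.

The preeclampsia and sepsis vital-sign criteria read the shared admission
vitals columns rather than duplicated `pe_*`/`sep_*` copies: one bedside
observation feeds both instruments, as on the paper form.

## Evaluation statistics

`evaluate_cohort()` excludes records lacking either the predictor or the
outcome listwise (with a logged count), cross-tabulates the dichotomy
against the composite morbidity outcome (logical OR of postpartum
hemorrhage, infection and preeclampsia before discharge), and reports:

* sensitivity, specificity, PPV, NPV, accuracy from the 2×2 cells, each
  `NA` if its margin is empty while the others are still computed;
* the relative risk `[tp/(tp+fp)] / [fn/(fn+tn)]` with the **Katz
  log-scale interval**
  `exp(log RR ± z · sqrt(1/tp − 1/(tp+fp) + 1/fn − 1/(fn+tn)))`. The
  interval method is a package choice (the original analysis does not name
  one); Katz is the standard large-sample interval for a cohort-style 2×2
  and the tests verify its ~95% coverage by simulation. A
  Haldane–Anscombe 0.5 correction is applied, and flagged, only when a
  cell is zero;
* the Pearson chi-square on the 2×2 via `stats::chisq.test`, Yates
  correction off by default (available by flag).

Printed report percentages are rounded half-up to one decimal, matching
clinical-table convention; all returned tibbles keep full precision. On the
replica cohort below, NPV is 331/363 = 91.18%, which prints as 91.2% — an
original report giving 91.1% is consistent with truncation, and the audit
tolerance accepts both.

The feasibility audit (`completeness_audit()`) classifies each form as
completed / partial / empty by whether all, some or none of the required
fields are documented; the default field list is the bedside form —
demographics (age, gravida, parity) plus the seven vitals. Likert
experience questions are summarised by the share of the `top_k` (default 2)
most favourable categories.

## The synthetic cohort generator

No record-level data from the original deployment is available, so
`generate_cohort()` emulates a cohort by **inverse (class-first)
construction**: each record draws its latent morbidity
(`Bernoulli(prevalence)`) and its intended triage class (positive with
probability `target_sensitivity` given morbidity, `1 − target_specificity`
otherwise), then receives values that realise the class exactly:

* *negative* records draw vitals uniformly inside a safe envelope that both
  scores 0 MEOWS points and fires no RI criterion (e.g. systolic 101–139,
  since 91–100 is a sepsis band; pulse 51–99, since 100–129 is one; urine
  ≥ 50 mL/h, since 30–49 is a preeclampsia band); a third of them carry one
  harmless 1-point component so low records are not uniformly zero;
* *positive* records draw one firing mechanism, uniform by default over a
  hemorrhage checklist flag, a preeclampsia laboratory/symptom criterion, a
  sepsis diagnostic criterion, or a pure vital-sign pattern totalling
  MEOWS 3 (three 1-point components that belong to no RI band). The
  mechanism mix is configurable because the true distribution of what drove
  positivity was never reported.

Because classes are guaranteed by construction, the round-trip invariant —
the package's own scorer and classifiers reproduce the intended class for
100% of classifiable records — is a hard test, not a statistical one.
Default parameters are the study conditions: prevalence 49/478,
sensitivity 13/45, specificity 331/354, completeness 363/79/36 of 478.
Demographics (age 28.30 ± 6.38, gravida 2.58 ± 1.91, parity 1.43 ± 1.67,
truncated normals) and district labels (28.2/28.5/29.1/13.6%) are cosmetic
stratification only and are never read by any classifier.

Masking emulates form incompleteness *after* the classification inputs are
fixed: partial forms mask demographic fields only (so masking can never
change the intended class), empty forms mask every form and checklist field
and are excluded by `triage()` as unclassifiable. Masking never touches the
latent outcome columns. What the generator deliberately does **not**
emulate: joint physiologic correlation between vital signs, time-series
trajectories, site effects, or morbidity that arises from the vitals
themselves — so a passing pipeline demonstrates the *plumbing and
arithmetic* on realistically structured tables, not clinical validity on
real patients.

`study_replica_fixture()` is the deterministic counterpart: 478 records
with form statuses exactly 363/79/36, 49 morbid records, and 399 records
with complete predictor and outcome whose cross-tabulation is exactly
(13, 23, 32, 331). The 79 non-analyzable records decompose as the 36 empty
forms plus 43 partial forms lacking all predictor fields, while another 36
partial forms miss only a demographic field and stay analyzable
(363 + 36 = 399) — the only deterministic split consistent with the
published margins under this package's exclusion rule.

## Reproducing the headline numbers

```{r replica}
fx <- study_replica_fixture()
ev <- evaluate_cohort(fx)
ev
completeness_audit(fx)[, c("n_completed", "n_partial", "n_empty")]
likert_summary(staff_experience_counts(), top_k = 2)
```

## Problem sizes and numerical checks

The test suite checks the scorer against an independently written if/else
transcription of the chart on 10,000 random observations spanning the full
admissible domains (with missingness), the RI classifiers against a
per-criterion max oracle on 400 random records, the Katz interval against
a 4,000-replicate bootstrap of the replica table and a 2,000-table
coverage simulation, and parameter recovery through the full
generate → score → triage → evaluate pipeline at n = 10,000 within three
binomial standard errors of the configured operating point. These sizes
make the Monte-Carlo tolerances tight relative to the effects being
checked while keeping the default suite quick on a laptop.

## Known limitations

* The band-table alignment for temperature, diastolic pressure,
  respiratory rate and urine output is a documented choice among the
  alignments consistent with the printed chart, not a verbatim fact.
* The intended tier of the duplicated ASAT/ALAT criterion is unknowable
  from the source; the conservative high-tier reading is used.
* The combination rule behind the published dichotomy is reconstructed;
  the `rule` argument exists precisely because it is not verifiable.
* The generator's independence assumptions (morbidity independent of the
  masking process, mechanism mix uniform) are simulation conveniences.
* No longitudinal escalation modelling: serial observations are scored
  independently.
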