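---
title: "The MIS-HF instrument: scoring model, validation statistics and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MIS-HF instrument: scoring model, validation statistics and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mishf)
```

## The instrument

The Maastricht Instability Score—Heart Failure (MIS-HF) is an additive
questionnaire for chronic heart-failure outpatients. A trained nurse walks
through 33 rows of clinical criteria — NYHA class, dyspnoea course, blood
pressure, heart rate and rhythm, weight course, oedema, angina grade,
NT-proBNP, electrolytes, renal function, haemoglobin, medication
up-titration, compliance, social support, depression signs and recent
heart-failure admissions — and each row that applies contributes 1 to 3
points. The total drives a referral recommendation: **0–2 points** is a
stable clinical condition, eligible for follow-up in primary care; **3 or
more** indicates instability and a need for continued specialist care. The
threshold was set conservatively, favouring specificity: it should be hard
for a genuinely unstable patient to look stable.

This package implements the instrument as a rule engine over a typed
per-patient record. Graded alternatives of one clinical dimension (the four
NYHA classes, the three dyspnoea states, the weight states, the angina
states, new versus chronic anaemia) are mutually exclusive by construction
of the input schema, so the 33 questionnaire rows collapse into 22 scored
items (`mishf_items()`). Everything else adds. Two design questions were
genuinely open and are resolved as follows:

* **Rhythm items add.** The rate criterion (sinus > 75/min or atrial
  fibrillation > 100/min), new onset, and symptomatic irregularity are
  separate rows with separate points and the instrument's total is a plain
  sum, so a patient with new, symptomatic, rapid atrial fibrillation scores
  2 + 2 + 2 = 6 from the rhythm dimension. The schema still prevents
  physically impossible combinations (a sinus-rhythm patient cannot be
  "new irregular"). No cap is applied because none is stated.
* **Hypertension is systolic-or-diastolic.** "BP > 140/85" fires when either
  limb exceeds its limit; symptomatic hypotension "< 90/50 with symptoms"
  requires both limbs below their limits *and* the symptom flag. This is the
  conventional clinical reading of the two notations; both cut-offs live in
  the threshold record (`mishf_thresholds()`) and can be audited or changed.

Two further rules matter in practice. The three renal sub-criteria
(creatinine > 220 µmol/l, creatinine risen > 25%, GFR < 30 ml/min) share one
row and one point, so the creatinine item fires at most once. The two
NT-proBNP rows (risen > 25% versus the previous value; level > 400 pmol/l,
i.e. > 3383 pg/ml) test different facts and may both fire.

### Missing laboratory values

Laboratory values are drawn only when clinically indicated, so missingness
is part of normal use. A laboratory item whose inputs are absent is returned
as *unassessed* with zero points — never an error. Because a missing lab can
only hide points, the per-patient result carries a `completeness` fraction
and an `underestimation_flag` that is raised when any laboratory item is
unassessed *and* the total is still in the stable range: exactly the case
where hidden points could flip the recommendation. When haemoglobin is
anaemic but the chronicity of the anaemia is unknown, the item scores as
chronic (1 point rather than 2) — the conservative reading that never
inflates a score from missing information. All boundary comparisons are
strict in the direction printed on the questionnaire (a potassium of exactly
3.5 mmol/l or a sinus rate of exactly 75/min does not fire).

### Angina beyond class 3

Unstable or CCS class 4 angina is not a questionnaire category; the study
excluded acute presentations. Such input is rejected with a validation error
that points to specialist care directly rather than being silently scored.

## Validation statistics

The statistics used to validate the instrument are implemented in the
package rather than borrowed, because they *are* part of the surface being
tested; standard library fits (`glm`) appear in the test suite as
independent cross-checks only.

**Odds ratios.** Every printed comparison is a 2×2 events/non-events table.
`odds_ratio_estimate()` computes the cross-product OR with a Woolf
confidence interval, $\exp(\ln \text{OR} \pm z \sqrt{1/a + 1/b + 1/c +
1/d})$, and a two-sided Wald p-value on the log OR. The Woolf form
reproduces the published intervals to the printed precision. When any cell
is zero the estimate is reported as undefined — matching the published
behaviour for the stratum with no cardiac admissions — and a
Haldane–Anscombe 0.5 correction is available behind an explicit option, not
as a default.

**Logistic regression.** `fit_logistic()` is a plain iteratively reweighted
least squares maximiser with a deviance-change convergence tolerance of
1e-8 and a cap of 100 iterations. On a saturated one-covariate model the
exponentiated slope equals the cross-product OR, which the tests verify to
1e-6 over a grid of small tables. Separation (including a constant outcome)
is detected by a diverging coefficient norm or fitted probabilities pinned
to 0/1, and reported as a flag rather than as spuriously huge finite
estimates. Rank-deficient designs are rejected with the collinear columns
named.

**Reliability.** Three statistics, with deliberately pinned-down
conventions:

* Cohen's kappa on the binary stable/unstable classification, from observed
  and marginal-chance agreement.
* The intraclass correlation on exact totals as **ICC(2,1)** — two-way
  random effects, absolute agreement, single rater — because the design is
  two interchangeable nurses each scoring the same patients once, and a
  systematic scoring shift between nurses should count as disagreement. The
  consistency form is exposed as an option.
* Cronbach's alpha on the per-item **point values** (a binary fired/not
  mode is available), with sample variances (denominator $n-1$) throughout.

## The synthetic cohort generator

No patient-level data accompany the instrument, so the generator exists to
make every stage testable end to end. It emulates the validation study's
*structure*: about 637 outpatients; per-item firing probabilities calibrated
once (by the shipped `scripts/tune_prevalences.R`, a bisection on a common
scale factor over plausible base prevalences) so that ~52% of patients land
in the stable class; referral adherence of 62% (stable→primary care) and
14% (unstable→primary care); and 1-year event probabilities of 10.9%
(stable) and 29.2% (unstable) for the composite endpoint, with component
rates for heart-failure admission, cardiac non-HF admission and death taken
from the per-class event proportions.

Three mechanics are worth knowing:

* **Fields are realised, then scored.** The generator samples which items
  fire and then draws clinical field values consistent with that pattern (a
  fired potassium item yields an out-of-range potassium; a quiet one, a
  value safely inside 3.5–5.0). Laboratory fields are then blanked at
  configured missingness rates, and the cohort is scored by the real
  engine, never by adding up the sampled pattern — so missingness, boundary
  conventions and exclusivity rules all act exactly as they would on real
  input.
* **Outcomes are a correlated union.** The published component counts sum
  to more than the composite, so components must overlap within patients.
  Each patient receives a shared standard-normal frailty; component $j$
  fires when $\rho L + \sqrt{1-\rho^2}\,E_j$ falls below $\Phi^{-1}(p_j)$,
  and $\rho$ is solved numerically (per score class) so the union
  probability equals the configured composite rate.
* **One seeded generator per run.** All randomness flows from the
  configuration's single integer seed (the second-rater draw uses a fixed
  offset so it is independent of, but reproducible with, the cohort draw);
  the same seed gives byte-identical CSV output.

The simulated second rater adds integer Gaussian noise (SD 1.2 by default)
to each total, clipped to the instrument's range, and the class is recomputed.
The noise scale was calibrated once so Cohen's kappa sits near the published
operating point of 0.65 (the acceptance band is 0.5–0.8). A single noise
scale cannot simultaneously reproduce the published kappa (0.65) and ICC
(0.92): matching kappa yields an ICC near 0.83. Kappa was preferred because
the classification drives the referral decision. The published reliability
values are calibration references only — the underlying 173-patient dual
ratings were never published, so they are not reproduction targets.

What the generator does **not** emulate: the real covariate structure (age,
sex, COPD, diabetes are drawn independently of the score, so they exist for
exercising adjustment code, not for reproducing confounding); correlations
between items (a cachectic patient is no more likely to have a high
NT-proBNP than anyone else); within-class dependence of outcome on the exact
total; and the baseline characteristics table of the study population.
Passing tests therefore show that the machinery is correct under the stated
generative model, not that the instrument discriminates on real patients.

## Numerical choices and problem sizes

* Woolf/Wald estimates are closed-form; `alpha_level` must lie strictly in
  (0, 1).
* IRLS: deviance tolerance 1e-8, max 100 iterations, weights floored at
  1e-10, separation at coefficient norm > 1e4.
* The frailty loading $\rho$ is solved with `integrate()` (rel.tol 1e-10)
  and `uniroot()` on [0, 0.999]; configurations whose composite rate is
  unreachable (above the independent union or below the largest component)
  are rejected at validation.
* Undefined statistics (zero cells, zero variance, total chance agreement)
  carry an explicit `defined = FALSE` flag and `NA` values, never a silent 0.
* Test and acceptance problem sizes are chosen to keep the full suite under
  a minute of simulation time while leaving Monte-Carlo noise well inside
  the asserted bands: coverage uses 2,000 replicated tables of 200 per
  group; the logistic/contingency grid uses 625 tables; cohort-level checks
  use 637 (the study size), 20,000 (effect recovery within ±0.5) and
  100,000 (convergence) patients; reliability checks use 500–2,000 subjects.

## Limitations

The package scores and classifies; it does not advise on treatment, doses,
or referral from primary *to* secondary care (untested for the instrument),
and the multivariable-adjusted estimates of the validation study are not
reproducible without the patient-level data. The scoring thresholds are
configurable, but the defaults are the instrument as published; changing
them produces a different instrument, and `max_possible_score()` plus the
validation suite should be re-examined after any change.
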