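---
title: "Virtual controls: methodology and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual controls: methodology and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualcontrols)
```

## The problem

School-based substance-use prevention trials increasingly cannot recruit
randomized control schools: schools decline the burden, widely disseminated
programs leave few naive comparison sites, and control arms that are
recruited often suffer selection bias and differential attrition. The
virtual-controls methodology replaces the recruited control arm with an
algorithmically generated counterfactual for every treated student, built
from large pooled normative survey data.

The method rests on two regularities in adolescent survey data: 30-day
substance-use prevalence rises steadily with age, and a small set of
psychosocial measures (beliefs about consequences, intentions to avoid use,
normative beliefs, refusal ease) is strongly inversely correlated with use,
making a composite of them a usable proxy for risk.

## The model

**Psych score.** Each survey item is coded onto a 0–10 scale with 10 the
theoretically most desirable response (reversing items whose raw order runs
the other way), and the student's psych score is the arithmetic mean of the
coded items. The default battery has 13 items (3 beliefs, 3 intentions, 4
normative beliefs, 3 refusal-ease); a score is treated as missing when fewer
than 7 items are present — a majority rule, configurable, since no standard
missing-item rule exists for this composite.

**Normative table.** From a pooled normative sample, the empirical quantile
of psych is computed at each percentile of a grid (default 0.5–99.0 in steps
of 0.5, i.e. 198 percentiles) for every age-month from 120 to 240 with at
least 20 records. Each percentile's values are then smoothed by ordinary
least squares as a quadratic in age,
$\mathrm{psych}(a) = \alpha a^2 + \beta a + \gamma$. Because the quadratics
are fitted independently they can cross; a post-fit pass re-sorts the
evaluated values within every age column so psych is non-decreasing in
percentile, and clamps to [0, 10]. The matching step requires this coherent
ordering. The full default table has 198 × 121 = 23,958 cells.

**Behavior probabilities.** For each 30-day behavior (alcohol, drunkenness,
cigarette, vaping) a logistic model is calibrated on the treated students'
pretests:

$$ P(\text{use}) = \frac{e^t}{1+e^t}, \qquad
   t = B_0 + B_{P}\,\mathrm{Psych} + B_{P\times A}\,(\mathrm{Psych}\times\mathrm{Age}) $$

with age in months. Age enters only through the product term; there is no
age main effect, and the package implements the formula exactly as written.
When a behavior has fewer than `min_positive` (default 20) positive pretest
cases the weights are unstable and the behavior is excluded — in young
cohorts this regularly happens to cigarette smoking.

**Matching ("pegging").** Each treated student is matched, using only their
pretest age and psych score, to the grid percentile whose table value at
that age is closest in absolute distance. Ties break toward the lower
percentile — the conservative direction, since lower percentile means lower
psych and higher estimated risk. The virtual case stays at that percentile
forever: at each later wave where the treatment case was surveyed, the
virtual psych is the table value at the pegged percentile and the treatment
case's age, and the virtual behavior probability follows from the logistic
weights. Later-wave self-reports are never consulted, so the virtual case
exists exactly when its treatment twin is observed — differential attrition
is eliminated by construction. Students younger than 120 months are excluded
(the pooled norms contain no one younger); observed psych scores above the
top curve clamp to the top grid percentile, and ages above 240 months clamp
to the table edge with a warning.

**Comparison.** Treatment self-reports (0/1) are compared with
virtual-control probabilities at the student level and aggregated
(unweighted means) to classrooms and schools. The package uses Welch's
unequal-variance t-test with Welch–Satterthwaite degrees of freedom — the
two sides have very different variances (Bernoulli vs model probabilities),
so the equal-variance test would be inappropriate; published work does not
name the flavor. Cohen's d uses the pooled standard deviation, oriented
control minus treatment so positive d is the protective direction. Subgroup
contrasts (boys/girls, Hispanic/non-Hispanic, White/non-White) use the
pooled two-proportion z statistic at the 95% level; virtual cases inherit
their twin's demographics, so both sides are the same students and equal in
size. Pre-to-post and pre-to-follow-up changes can be dichotomized into
increase flags for external multi-level modelling; fitting those models is
out of scope here.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| percentile grid | 0.5–99.0 by 0.5 (198) | published grid size; the accompanying "0.5th through 95.5th" phrase implies 191 and is internally inconsistent with the stated 198 × 121 cell count, so the count is taken as authoritative; configurable |
| min records per age-month | 20 | below this the empirical quantiles are too noisy; sparse ages are covered by the fitted curve |
| quantile rule | linear interpolation (type 7) | unstated in the source methodology; R's default keeps cells reproducible |
| `min_positive` | 20 | prevalence guard for logistic stability ("too few cases") |
| `min_items_required` | 7 of 13 | majority rule for a missing psych score |
| tie-break | lower percentile | conservative (higher estimated risk) |
| school aggregation | student-weighted mean | mean over the school's students; a class-mean-of-means option exists, and the two differ with unequal class sizes |

## What the synthetic generator emulates

`generate_norm_pool()` draws records with uniform ages over 120–240 months
and latent percentiles uniform on (0, 100); psych is the generating curve
value plus Gaussian within-percentile noise (default sd 0.25), clamped to
the scale. The default curve family
$\mathrm{psych}(q, a) = 6.5 + 3.4q^{0.35} - 5.5(1-q)^{1.2}(0.7s + 0.3s^2)$,
$s = (a-120)/120$, is exactly quadratic in age, declines everywhere, and
declines fastest at low percentiles; it is non-crossing by construction and
puts the median near 9.2 at age 120, consistent with published normative
curves for these composites.

`generate_trial()` emulates a two-cohort fifth-grade trial: pretest at mean
age 130 months (sd 4), posttest +2 months, follow-up +10 months; 48.5%
boys, 14.9% Hispanic, 59.4% White; nested schools > classrooms > students.
Each student's realized psych per wave is the table value at their latent
percentile plus trait scatter (default sd 0.25); behaviors are Bernoulli
draws from the logistic model at the realized psych, with the published
alcohol/drunkenness/vaping weights as generating defaults and a synthetic
near-zero cigarette set that exercises the prevalence guard. Item responses
are generated around the realized psych with the noise scale solved in
closed form from a Cronbach-alpha target: the `"study-like"` preset targets
alpha 0.681 (the reliability such composites achieve in live fifth-grade
samples), `"norms-like"` targets 0.90. Attrition is dominated by
whole-school dropout (default 70% of the attrition on the school margin,
retention 33.5% at posttest and 24.3% at follow-up), reflecting that in
school trials the main loss is schools, not students, declining. A
`"top_heavy"` latent-percentile preset (13% at the top ranking, ~70% below
the 60th percentile) mirrors the skewed percentile distributions live
cohorts produce.

What the generator does *not* emulate: calendar effects (COVID-era school
closures by cohort-year), officer/instructor characteristics, item-level
nonresponse patterns, or correlated measurement error across items. Passing
tests on synthetic cohorts therefore demonstrate the algorithm's internal
consistency and statistical calibration under its own assumptions, not
fidelity to any particular live sample.

## Numerical and design choices

- **Non-crossing by re-sorting.** Independently fitted quadratics are
  re-sorted within each age column rather than constrained during fitting;
  this preserves each percentile's marginal fit while guaranteeing the
  monotone ordering matching requires.
- **Serialization precision.** Norm tables are written with 17 significant
  digits so a write–read round trip reproduces evaluations to better than
  1e-12.
- **Degenerate comparisons.** Zero variance on both sides with equal means
  yields t = 0, d = 0; with unequal means the contrast is flagged
  degenerate instead of fabricating a statistic.
- **Worked-example discrepancy.** The published worked example's alcohol
  probabilities (1.20%, 1.58%, 4.61%) are reproduced exactly by the printed
  alcohol weights. Its drunkenness (0.02/0.02/0.03%) and vaping
  (0.04/0.04/0.05%) probabilities are *not* reproducible from the printed
  weights, whose Psych×Age entries are rounded to 0.000 (they imply ~0.25%
  and ~0.41%); the package documents this and uses only the alcohol triplet
  as an exact reference.
- **Null calibration regime.** The type-I calibration of the student-level
  Welch comparison is checked on model-correct null cohorts: zero program
  effect, students exactly on their percentile curves (trait scatter 0),
  high-reliability battery, true generating weights, since calibration is
  defined under a correctly specified null. The check uses 200 cohorts of
  1,000 students and accepts within the 99% binomial band around 5%
  (2.5%–8.5%); observed rates sit near 5.5%. Weight *fitting* is validated
  separately by parameter recovery at 50,000 pretests, because a
  1,000-student fifth-grade cohort carries only ~20 positive alcohol cases
  — exactly the prevalence-guard boundary.
- **Test problem sizes.** The cached test table is fitted to a 60,000-record
  synthetic pool; end-to-end recovery uses 4,000-student cohorts; matching
  equivalence uses 1,000 randomized small tables. These sizes keep the full
  suite under a minute of simulation while leaving Monte-Carlo error well
  inside the asserted tolerances.

## Known limitations

- **Anticonservatism under trait scatter.** When students genuinely drift
  around their percentile curves (the generator's default scatter, sd 0.25),
  the student-level null rejection rate rises to roughly 9% rather than 5%:
  observed scores past the top curve clamp matches downward, and the
  convexity of the logistic at low prevalence inflates virtual estimates.
  Users should read small positive effects near the significance boundary
  with this in mind.
- **Attenuation.** Calibrating the logistic on noisily measured psych
  scores attenuates the psych slope relative to the latent relationship;
  at a reliability of 0.681 the attenuation is material. This mirrors the
  live-data situation, where pretest psych–behavior correlations are far
  weaker than in pooled norms.
- **Mixed-scale comparison.** The t-test compares observed 0/1 outcomes
  with model probabilities; this is the method's own design, and both sides
  estimate a prevalence, but the control side's variance is model-derived,
  not sampling-derived.
- **No multiple-testing correction** is applied across the 36 subgroup
  tests; the published analyses applied none, and the package reports the
  per-test flags.

## A minimal run

```{r, eval = FALSE}
pool <- generate_norm_pool(norm_pool_spec(n_records = 60000, seed = 11))
tab <- build_norm_table(pool)
trial <- generate_trial(trial_spec(seed = 3), tab)

td <- tempdir()
write_surveys(trial, file.path(td, "surveys.csv"))
write_norm_table(tab, file.path(td, "norms.csv"))
res <- run_pipeline(run_config(survey = file.path(td, "surveys.csv"),
                               norm_table = file.path(td, "norms.csv"),
                               out_dir = file.path(td, "out")))
res$results$levels
```
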