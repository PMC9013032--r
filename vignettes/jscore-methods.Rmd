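---
title: "Severity scoring from diagnosis codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity scoring from diagnosis codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring model

`jscore` estimates the probability that an adult inpatient encounter is
a high-severity case (4-level severity of illness 3 or 4, versus 1 or 2)
from the diagnoses coded on the encounter. Two scores are produced per
encounter: the discharge score (J_Score), computed from every coded
diagnosis, and the admission score (J_Score_POA), computed only from
diagnoses flagged present on admission (POA `Y` or `W` by default) plus
codes on the POA-reporting-exempt list. Because the admission code set
is a subset of the discharge set, admission features never exceed
discharge features — a package invariant that the test suite checks on
random cohorts.

Predictors are built from three pluggable code maps:

* **Body-system CC/MCC ordinals.** Each ICD-10-CM code belongs to one of
  18 body systems. Per system the encounter gets level 0 (no code in the
  system), 1 (codes present, none CC/MCC) or 2 (at least one CC/MCC
  code). The principal diagnosis participates here: the aim is to
  capture every affected system. This choice is configurable in spirit —
  the indicator builders accept any diagnosis subset — and is the one
  genuinely open design point in the feature layer, since comorbidity
  conventions exclude the principal diagnosis while body-system burden
  arguably should not.
* **Elixhauser comorbidity flags.** One binary flag per category in a
  30-name registry, set by secondary diagnoses only, following the
  standard construction of comorbidity measures from administrative
  data. The registry defaults to the classic 30-category set with
  hypertension split into uncomplicated/complicated and no
  cardiac-arrhythmia category; it is an argument everywhere, because
  category definitions drift across releases of the upstream software.

CC/MCC status is treated as a property of the code alone; the
payment-grouper refinement that conditions CC status on the principal
diagnosis is deliberately out of scope, as are age and procedure
adjustments.

The model is a binomial GLM with logit link. Ordinal predictors enter
through orthonormal polynomial contrasts over equally spaced scores —
for three levels, the linear column proportional to (-1, 0, 1) and the
quadratic proportional to (1, -2, 1); binary flags enter through the
two-level contrast. "Orthogonal polynomial regression" therefore means:
the contrast basis is orthogonal, the model space is exactly that of a
dummy-coded logistic regression, and the fitted probabilities are
identical between the two encodings (checked to 1e-8 in the tests).
The contrasts buy interpretability (trend vs curvature per system) and
a well-conditioned design, not a different model. Three variants are
compared: the full model (18 ordinals + 30 flags, 48 predictor
variables, 66 design columns), the comorbidity model (30/30) and the
body-system model (18/36). No interactions are included.

## Fitting and numerical choices

The fitter is iteratively reweighted least squares with the intercept
always included, convergence declared when the relative deviance change
drops below 1e-8 (at most 100 iterations), and standard errors from the
inverse of the final weighted information matrix. Starting values are
the intercept-only solution. Two degenerate regimes are handled
explicitly:

* a rank-deficient weighted least-squares step (a predictor constant in
  the training data) is a fatal error naming the likely cause;
* runaway coefficients with no deviance plateau — quasi-separation —
  produce an error advising the ridge option (`ridge > 0` penalizes the
  non-intercept coefficients and is off by default). A fit that reaches
  a deviance plateau with a few saturated cells is returned as-is,
  matching standard GLM behaviour; its fitted probabilities are stable
  even when individual boundary coefficients are large.

Classification uses the cutoff minimizing the Euclidean distance from
the training ROC curve to the corner (0, 1); only realizable cutoffs
(distinct score values) are candidates and ties break toward the larger
threshold, the more conservative high-severity call. Test-set accuracy,
FPR and FNR are computed at the training cutoff with the rule
`score >= cutoff -> high` (non-strict, fixed). ROC areas use the
trapezoidal rule with tied scores grouped at one threshold, which makes
the area equal to the Mann–Whitney concordance statistic; the
precision–recall area uses the average-precision step rule rather than
trapezoidal interpolation, which is known to flatter PR curves. The
train/test split is simple random at 3:1 (stratified splitting is
available but off by default). Table-1-style cohort comparisons use a
Welch two-sample test for age and chi-square tests for categorical
variables.

Encounters with zero diagnoses are retained and score at the
intercept-only probability: the scoring function is total and
deterministic.

## What the synthetic generator emulates

Nothing proprietary ships with the package, so the generator stands in
for both the reference content and the cohort. Its defaults are the
study conditions the package is tested under, chosen once:

* a code universe of 18 x 12 codes; 20% CC and 10% MCC per code, with
  every body system guaranteed at least one severe code and every
  comorbidity category at least one code (real maps have no empty
  categories, and an empty one would make the design rank deficient by
  construction); 5% POA-exempt codes;
* comorbidity attachment probabilities set so encounter-level
  prevalences land near commonly reported values for the top categories
  (hypertension ~26%, fluid/electrolyte disorders ~24%, deficiency
  anemia ~18%, chronic pulmonary disease ~17%);
* one principal plus Poisson secondaries, 10 diagnoses per encounter on
  average; POA flags mostly `Y` (94%), with CC/MCC codes even more
  likely to be present on admission — acute severe conditions rarely
  arise only after admission, and in a hospital running a
  documentation-improvement program most non-POA severity capture flows
  through chart review rather than routine coding;
* a body-system-variant truth model with linear coefficients cycling
  over 2.2/1.4/1.0, small quadratic terms, and an intercept placing the
  marginal high-severity rate near 44%, which also yields the
  characteristic strongly bimodal score histograms with a few percent
  of scores displaying as 1 at two decimals;
* demographics (mean age ~49, ~53% female, a typical race mix, 21
  facilities, 12 discharge months) exist only to exercise the
  descriptive and benchmarking reports.

Labels are drawn as Bernoulli at the true logistic probability of the
phase's features, then dressed up as 4-level SOI (uniform within
{1,2} or {3,4}) because the method consumes only the binarized outcome.
Admission and discharge labels are drawn independently given their
features; real SOI pairs are correlated, but no package computation
couples the two phases, so the simplification is harmless.

The CDI process marks for review every encounter whose latent admission
probability exceeds a threshold (0.35 by default, reviewing roughly a
third of the cohort), flags half of reviewed cases as queried, and
injects Poisson(3) non-POA CC/MCC codes per reviewed case into body
systems not already at level 2 — a documentation query captures
severity that was missed, not severity already on the chart. Because
severity assignment works from the final coded record, the discharge
truth and SOI of augmented encounters are redrawn from the post-capture
features; admission truth is untouched. This feedback matters: without
it the discharge model would be trained on features systematically
inconsistent with their labels and its coefficients visibly attenuate.
With it, the generator reproduces the qualitative landscape the scoring
system is designed to expose — reviewed cases show high admission
scores and a large J_Score minus J_Score_POA gap, non-reviewed cases
show nearly equal scores, and the cohort-level mean gap of roughly 0.1
is concentrated in the reviewed stratum.

What the generator does **not** emulate: real ICD-10-CM semantics,
code co-occurrence structure, facility case-mix differences beyond a
label, pediatric patterns, or the grouper's procedure- and
age-dependent severity logic. Passing tests therefore demonstrate that
the pipeline recovers known structure under its own assumptions — not
that any particular accuracy will be achieved on real claims.

## Problem sizes and determinism

Test and acceptance runs use cohorts of 500–20,000 encounters for
pipeline checks, 50,000 for parameter recovery (where at least 95% of
recovered coefficients fall within 3 estimated standard errors of
truth), and 10,000 for the feature-dominance scan. All randomness flows
from explicit integer seeds: the generator derives its map, encounter
and CDI streams from one root seed, evaluation seeds the split
separately, and rerunning any step with the same inputs is
byte-identical (the CLI records content hashes in per-command
manifests to make drift visible).

## Known limitations

* CC/MCC status is unconditional on the principal diagnosis; scores
  from real FY code lists will differ slightly from grouper-aware
  logic.
* The model needs refreshing whenever the underlying code maps change;
  the `version_label` carried from the maps into every model and
  report exists to make stale pairings auditable.
* Unpenalized maximum likelihood can sit on the boundary for rare
  feature cells in small cohorts; the ridge option is the escape
  hatch, at the cost of exact encoding-equivalence.
* The "score displays as 1" convention is a reporting threshold
  (>= 0.995 by default, configurable), not a statement that any
  logistic probability equals 1.
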