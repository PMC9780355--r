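---
title: "Confounder-mediated shortcut learning: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounder-mediated shortcut learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortcutsim)
```

## The question the package answers

When a model trained on clinical images appears to predict a demographic
attribute such as race, how much of that performance can be manufactured
purely by the composition of the training cohort?  `shortcutsim` answers
this with a fully synthetic, analytically anchored pipeline: cohorts in
which the coupling between a binary label and a binary confounder is a
tunable parameter, predictors whose achievable performance on every
attribute is known by construction, and a closed-form expression for the
AUROC a confounder-only scorer attains at each coupling strength.

## The generative model

Each synthetic patient has sex (1 = male), continuous age in years with
its binarization at 65 (`age_group`), binary race (1 = white), 17 binary
comorbidities, and one feature vector per echocardiographic view.  The
feature vector is the surrogate for "whatever an imaging model could
extract": within each view's block of `feature_dim` standard-normal
coordinates, sex, age group and race shift the mean along the first three
(orthonormal) axes by their separations `d_sex`, `d_age`, `d_race`, using
±½ codings.  Three consequences matter:

* the best possible scorer for an attribute with separation *d* is the
  projection onto its axis, with AUROC Φ(d/√2) (`auc_for_separation()`);
  `separation_for_auc()` inverts this, so a task can be calibrated to any
  target AUROC;
* `d = 0` means the attribute is *exactly* unpredictable from features —
  the ground truth needed to interpret a nonzero test AUROC as shortcut
  learning;
* attribute signals are orthogonal, so nothing leaks between tasks except
  through cohort composition, which is the quantity under study.

Age is drawn from a Normal(`age_mean` = 66.5, `age_sd` = 16.4) truncated
to [18, 100].  Because a cohort specification fixes both the marginal
probability of `age_group` and the hard rule `age_group == (age >= 65)`,
the generator draws the group first (Bernoulli `p_old`) and then the age
from the truncated Normal restricted to the matching side of 65.  This
honours both constraints exactly; the cost is that the *unconditional*
age density is a mixture reweighted by `p_old`, which we accept because
the binarized group, not the age density, drives the confounding design.
`p_old` defaults to 0.5 so that age-group behaves as a balanced, fully
controllable confounder, symmetric with sex and race; the defaults
`p_male = p_white = 0.5` are chosen for the same reason.  Study-like
marginals (e.g. 55.7% male, 68.8% white) can be requested explicitly.

Comorbidities are drawn per condition as independent Bernoullis at the
race-stratified prevalences shipped in
`inst/extdata/comorbidity_prevalence.csv` (17 cardiovascular and systemic
conditions; proportions per white/black/asian stratum).  Non-white
patients are assigned to the black or asian stratum with probability
0.652 / 0.348, the relative size of those groups in the reference cohort,
unless a `stratum` column overrides the assignment.  Only marginals are
recorded in the source table, so any correlation structure between
conditions would be invented; independence is therefore declared rather
than claimed realistic — see "What the generator does not emulate".

## Bias-controlled cohorts

`construct_biased_cohort()` realizes the coupling parameter *b* ∈
[0.5, 1]: among label-positives a fraction *b* has confounder = 1, among
label-negatives that fraction is 1 − *b*; label prevalence is
`label_balance` (default 0.5) and the total is exactly `n_train` at every
*b*, so sweep comparisons never confound bias with sample size or class
imbalance.  Fractional cell counts are resolved by largest-remainder
rounding (ties to the earlier cell), which keeps the total exact and
every conditional count within one of its real-valued target.  Sampling
within a (label, confounder) cell is uniform without replacement; an
infeasible request fails with an error naming the exhausted cell.
Splitting is by patient (`split_by_patient()`), with exact partition
sizes by the same rounding rule, so no patient can appear on both sides
of a train/test boundary.

The label balance of 50/50 is a design choice: the source cohorts'
subgroup tables are not available, and balancing isolates the
confounding effect from class-imbalance effects.  It is configurable.

## Predictors

The imaging models are replaced by deliberately simple surrogates: a
ridge-penalized logistic regression for binary targets (cross-entropy
loss), ridge least squares for age (L2 loss), and an unpenalized logistic
stacking of per-view scores for the ensemble.  The claims under study
concern task *predictability* (AUROC), not architecture, and a linear
model is Bayes-optimal for the Gaussian surrogate features, so nothing is
lost at the level the analysis operates on.  No video architecture,
optimizer schedule, or GPU code is reproduced.  The ridge penalty is weak
(`lambda = 1e-3`) — enough to stabilize near-separable fits at extreme
bias without visibly attenuating calibrated AUROCs; fits use a fixed
convergence tolerance (`thresh = 1e-9`), making training deterministic
given data and hyperparameters.  Any object honouring the scorer contract
(numeric score per row, higher = more positive) can replace the linear
surrogate without touching pipeline code.

## Metrics and uncertainty

AUROC is the Mann–Whitney estimator computed from midranks (ties credited
½), identical to the brute-force probability that a random positive
outscores a random negative; the test suite checks exact agreement with
an all-pairs oracle.  MAE is the mean absolute residual in years.
Confidence intervals are percentile bootstrap over resamples of test
*patients* (the resampling unit matches the split unit), 10,000
replicates by default, 1,000 in the sweep defaults to keep experiment
turnaround short.  The percentile method was chosen over BCa as the
simplest defensible reading of "bootstrapped samples"; a bootstrap
replicate containing a single class is redrawn (with a retry cap and a
count recorded on the result).  Degenerate inputs behave predictably:
perfectly separated scores give a collapsed interval at 1, single-class
test sets are an error, not an NA.

## The shortcut oracle

For a scorer carrying only confounder signal of quality *A*, evaluated on
a population with the same bias *b* as training, conditioning a random
positive–negative pair on each member's confounder cell yields

AUC(b, A) = b²·A + (1 − b)²·(1 − A) + b·(1 − b),

with AUC(0.5, A) = 0.5, AUC(1, A) = A, nondecreasing in *b* for
A > 0.5, and the reflection AUC(1 − b, A) = 1 − AUC(b, A) under the
extension below 0.5 (aligning the opposite confounder level flips the
ranking).  `run_bias_sweep()` attaches this prediction whenever the label
carries zero direct signal and the test cohort shares the training bias.

The same-bias evaluation convention is itself a design decision.  The
composition of the held-out sets in the motivating sweep experiments is
not recorded, so both conventions are implemented: `test_bias_mode =
"same"` (default; the closed form applies, and at *b* = 1 the label is
identical to the confounder at test time too) and `"fixed"`, which
evaluates every grid point on a cohort at one fixed bias (typically 0.5,
where a confounder-only model must fall to chance).  No closed form is
shipped for the fixed mode; it is supported in simulation only.

## The comorbidity benchmark

`run_comorbidity_benchmark()` simulates a cohort from the packaged
prevalence table, fits a logistic regression predicting white vs
non-white from the 17 conditions (plus age and sex as covariates by
default — both simulated independently of race, hence signal-free, and
removable with `include_age_sex = FALSE`), and reports held-out AUROC
with a bootstrap interval.  Because real comorbidities are correlated and
the simulation draws them independently given race, the benchmark brackets
rather than reproduces what the same regression attains on real records;
the test suite asserts the band [0.55, 0.70], not a point.

## What the generator does and does not emulate

It emulates the statistical skeleton the confounding analysis needs:
binarized demographics at tunable marginals, per-attribute predictability
calibrated in AUROC units, race-stratified comorbidity marginals, and
exact bias-controlled cohort composition.  It does **not** emulate pixel
data, view-classification noise, intra-patient correlation across repeat
studies (each synthetic patient contributes one record), correlations
among comorbidities, correlations between comorbidities and the imaging
features, residual real-data confounding (a real sweep's low end can sit
slightly above chance, e.g. 0.53, where the single-confounder synthetic
pipeline attains 0.50), or nonlinear feature–attribute relationships.
Passing tests therefore demonstrate the *mechanism* — cohort bias alone
moves label AUROC along the predicted curve — not any claim about what a
particular imaging dataset contains.

## Problem sizes and numerical tolerances

The package's own experiments use n_train = 4000, n_test = 5000,
feature_dim = 8, a bias grid 0.5–1.0 in steps of 0.1, and populations of
6 × (n_train + n_test) patients, which keeps every cell feasible at the
default marginals up to *b* = 1.  Endpoint checks average 3–5 seeds;
at these sizes the per-seed AUROC standard error is ≈ 0.006, so means sit
within ±0.02 of their analytic anchors.  Monte-Carlo agreement tests run
at n = 20,000 with three Hanley–McNeil standard errors as tolerance;
bootstrap coverage is checked over 200 repetitions at n = 400 and 1,000
replicates.  Calibration inverses are exact to 1e-10 over a grid of
AUROCs; AUROC-estimator agreement with the pairwise oracle is exact to
1e-12 at n ≤ 50.

## Known limitations

Single confounder per sweep (multiple simultaneous confounders can be
simulated but have no closed form here); linear surrogates only out of
the box; the comorbidity benchmark's independence assumption; the
`p_old`-conditional age mixture noted above; and percentile (not BCa)
bootstrap intervals, which at small n can undercover slightly.
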