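---
title: "Modeling and measuring visuo-proprioceptive coupling in tool use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring visuo-proprioceptive coupling in tool use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpcoupling)
library(dplyr)
```

## The problem

In tool use — steering a cursor with a hand you cannot see — vision reports
the position of the tool's effective part and proprioception the position
of the hand. The two refer to different objects, so they are not fused into
one percept, yet they interact: each estimate is pulled toward the other.
This partial interaction is *sensory coupling*. Its strength is naturally
expressed as a proportional bias: when the visual feedback is rotated by
`x` degrees relative to the hand, a judgment of hand direction that deviates
by `b·x` degrees toward the cursor has bias `b` (0 = independence, 1 = full
visual capture).

This package implements that framework end to end: a weighted-average
coupling model and its variance consequences, a generative simulator of a
three-stroke visuomotor-rotation task, a geometric implicit measure of the
felt hand direction, regression-based bias estimation with two-level
outlier screening, and the group-level inferential battery, including
trial-history (sequential) effects.

## The coupling model

Let `P` be the unbiased proprioceptive signal and `V` the visual one, with
independent zero-mean noises and variance ratio `r = var(V)/var(P)`. The
coupled proprioceptive estimate is the weighted average

$$P' = (1 - b)\,P + b\,V,$$

so its variance relative to the unbiased one is

$$\frac{\mathrm{var}(P')}{\mathrm{var}(P)} = (1 - b)^2 + b^2 r ,$$

a strictly convex parabola in `b` with minimum at `b* = 1/(1+r)`, where the
relative variance is `r/(1+r)` — the inverse-variance weight of classical
cue integration. Two consequences matter for interpreting the behavioral
data. First, *any* bias below `2/(1+r)` reduces variance, so even the more
precise (visual) estimate profits from a weak coupling toward
proprioception. Second, a stronger bias toward the more reliable modality
buys lower variability, which is how an age-related *decrease* in judgment
variability can accompany an age-related *increase* in bias.

```{r curves}
coupling_curves(b = seq(0, 1, 0.25), r = c(0.2, 0.7)) |> head(5)
optimal_bias(c(0.2, 0.5, 1))
```

The closed form above assumes independent noises; a noise correlation
`rho` can be supplied (`relative_variance(b, r, rho)`), adding the
cross-term `2 b (1-b) rho sqrt(r)`. The default is 0 — the analysis never
relies on correlated noise, but the generalization is exposed rather than
baked in. Both coupling directions come from the same function: the visual
panel of the variance-reduction picture just uses the reciprocal ratio.

## The task and its geometry

Each trial is a three-stroke movement on a digitizer: start position to a
first target T1, then out to a remembered second target until a 15-cm
stopper ring ends the stroke, then back to the remembered T1 without visual
feedback. Only during the second stroke is the cursor shown, rotated by one
of ±5, ±10, ±15, ±20, ±25, ±30 degrees. Afterwards the participant reports
either the cursor direction or the hand direction at the end of the second
stroke — the *explicit* judgments, 72 trials per type, randomized, 144
trials in all.

Angles use one convention throughout: 0° along the start-to-T1 axis, CCW
positive, wrapped to (−180, 180], and stored in degrees (radians appear
only inside trigonometric kernels). All analyzed quantities are angular
*deviations* (judged − actual), so the choice of zero axis cancels.

The *implicit* measure exploits error propagation into the return stroke.
If the felt hand position at the end of stroke 2 is rotated by α′ about T1
relative to the true position, the return stroke — aimed at T1 from the
felt position — inherits that rotation. `implicit_angular_deviation()`
computes α′ as the signed angle from the outward line (T1 → stroke-2
endpoint) to the return line translated so that the stroke-3 endpoint sits
on T1. Two properties make this measure well-behaved, and both are enforced
by tests at 1e−9 degrees: the construction is exactly invertible
(`make_return_endpoint()` is its generative inverse), and α′ is invariant
to the length of the return stroke, so undershoot or overshoot of the
return does not masquerade as felt-position rotation. An equivalent reading
takes the direction from T1 to the felt position; under the parallel-shift
construction the two coincide. Trials with a zero-length stroke are
degenerate: they are excluded with a logged warning, never imputed.

## The generative simulator

`simulate_cohort()` produces trial tables with the design exactly (144
trials; every rotation × judgment-type pair 6 times; a seeded uniform
permutation per participant) and the reported statistical structure. Per
trial, the target is uniform in (−60, 60)°, the hand direction is
`target − rotation` plus motor noise (the participant steers the rotated
cursor onto the target), the cursor is `hand + rotation`, and each
judgment deviates by `slope·rotation + intercept + noise`. The implicit
deviation is generated on *every* trial — the return movement precedes the
instruction naming the explicit judgment type — and is materialized as a
stroke-3 endpoint, so the estimation side must recover it through the
geometry, not from a shortcut column.

Default presets encode the study conditions:

| parameter | young | older | status |
|---|---|---|---|
| explicit-hand slope (deg/deg) | 0.63 | 0.75 | reported group mean |
| explicit-cursor slope | −0.08 | −0.07 | reported group mean |
| implicit slope | 0.31 | 0.30 | reported group mean |
| explicit-hand intercept (deg) | +3 | +3 | "a few degrees" CCW; exact value assumed |
| other intercepts | 0 | 0 | reported as not different from zero |
| explicit-hand noise SD (deg) | 10 | 8 | assumption (see below) |
| cursor / implicit noise SD | 4 / 4 | 4 / 4 | assumption |
| motor noise SD / return-length CV | 4 / 0.05 | 4 / 0.05 | assumption |
| sequential deltas (deg/deg) | +0.015 / −0.015 | same | assumption, ×2 when repeated |
| outlier rate / shift | 0.005 / 40° | same | assumption |
| participants | 16 | 19 | retained sample sizes |

Intra-individual noise SDs are not published as numbers (only as a figure),
so the defaults are declared assumptions chosen once to reproduce the
reported *ordering*: explicit hand judgments far noisier than the other
two, and — uniquely for that judgment — noisier in the young than in the
older group. Sequential deltas are likewise free parameters reproducing the
reported directions: explicit biases strengthen after a same-type judgment
(strength-signed, so cursor slopes get more negative), the implicit bias
weakens after explicit *hand* judgments, and both effects double after a
repeated preceding type. They are kept small so the marginal slopes stay at
the preset group means (the expected marginal shift is ≈ 0.011 deg/deg).
Gross outliers (rate 0.5%, ±40°) give the screening machinery something
realistic to find, at the order of magnitude of removal rates reported for
the human data (0.3–0.5%).

Seeding is hierarchical: one master seed; per-participant child seeds are
derived by a counter (`(seed·1000003 + 7919·k) mod 2^31−1`), so each
participant's data are reproducible and order-independent. The preset
validator accepts zero SDs: the degenerate noiseless generator is the exact
oracle for several tests.

What the generator does **not** emulate: movement kinematics (speed
profiles, reaction times, the multi-second delay before explicit
judgments), memory decay of the judged direction, within-session learning
or fatigue, and any dependence of judgment noise on rotation magnitude.
Passing recovery tests therefore shows that the pipeline is an unbiased,
correctly calibrated inverse of *this* measurement model — not that the
model captures every feature of real behavior.

## Estimation and screening

For each participant and judgment kind (cursor-explicit, hand-explicit on
the matching 72 trials; hand-implicit pooled over all 144), the angular
deviation is regressed on the rotation by OLS: the slope is the
proportional bias, the intercept the rotation-independent offset. The
closed-form simple regression is used (it is exercised tens of thousands of
times in simulation studies) and is verified against `stats::lm` in the
test suite.

Screening follows the study's two levels and order:

1. **Trials** — a *single* pass per participant and kind: fit once, remove
   trials outside predicted ± 3 residual SDs (`sqrt(RSS/(n−2))`). The
   iteration language of the source procedure attaches to the participant
   level, so the trial screen is deliberately not iterated. Under clean
   Gaussian noise this removes ≈ 0.27% of trials; with zero residual SD it
   removes nothing (logged).
2. **Participants** — per judgment kind, with both age groups pooled, bias
   parameters outside mean ± 3 SD are excluded and the mean/SD recomputed
   until a pass finds no outlier. A participant excluded for any kind is
   excluded from all analyses. The iteration count reported is the number
   of passes that removed someone. A small-sample caveat is worth knowing:
   the largest attainable z in a sample of n is (n−1)/√n, so a 3-SD rule
   cannot flag anything for n ≤ 10 — it is designed for the pooled cohort
   (n = 35+).

## Inference

ANOVAs are univariate mixed-design fits through `stats::aov()` with
`Error(participant/(within factors))` strata, reproducing the standard
split-plot F tests (the paired-t identity F = t² for 2-level within factors
is in the test suite, as is a hand-decomposed sums-of-squares oracle).
Sphericity corrections are off by default for fidelity to the reported
uncorrected F's; a Greenhouse–Geisser option computes epsilon from the
group-centered covariance of the within-cell scores. Two-sided tests
throughout; Bonferroni post-hocs multiply raw p by the number of
comparisons and cap at 1.

For sequential effects, trials are classified by the preceding trial's
explicit-judgment type and whether that type had just run ≥ 2 trials
(`repeated`) or 1 (`once`); the threshold is configurable. The first trial
is unclassifiable; breaks do not reset history (configurable design choice:
the procedure description does not mention resetting). One statistical
subtlety: because the preceding run is sampled in a length-biased way,
"once" and "repeated" are *near-balanced* (P ≈ 1/2 each), not 2:1 as naive
run-length statistics might suggest. Subset biases are fitted per
participant × kind × category; for the strength ANOVA the cursor-explicit
slopes are sign-flipped so larger always means stronger coupling (the raw
output keeps natural signs). Subsets with fewer than 3 distinct rotations
are dropped with a warning.

## Numerical choices and degenerate inputs

- Wrapping maps to (−180, 180], with −180 folded to +180; the antisymmetry
  of deviations holds everywhere except that boundary.
- Coincident points (zero-length strokes) raise errors in direction
  computations and NA-with-warning in the vectorized implicit measure.
- Zero residual SD disables trial screening for that fit; a constant bias
  vector terminates participant screening immediately.
- `fit_bias` requires ≥ 3 distinct rotations; `one_sample_t` and
  `pearson_corr` reject zero-variance input rather than returning NaN.
- Unbalanced ANOVA designs are rejected up front with a clear message
  rather than silently producing Type-I/Type-III ambiguity.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at the study's own scale
where that is cheap — full 35-participant cohorts (5 040 trials) for
parameter recovery, 10⁶-draw Monte-Carlo oracles for the variance algebra,
10⁴ random constructions for the geometry round trip — and at reduced scale
where only calibration matters: the type-I-error check of the group effect
uses 2 000 replicates of 4+4-participant cohorts, since the test's level
does not depend on group size. These sizes are the package's own choices
and are stated here so they can be revisited.

## Known limitations

- The noise SDs and sequential-delta magnitudes of the default presets are
  assumptions (only their ordering is anchored); recovered values should be
  compared against whatever preset generated the data, not against
  literature values.
- The ANOVA error structure for the four-way sequential design uses the
  standard participant-within-group strata; other error-term conventions
  exist and would change borderline F's.
- The implicit measure assumes the return stroke is aimed at the remembered
  T1 from the felt position with no independent directional bias; any such
  bias would load on the intercept, not the slope.
- Robust-regression alternatives to the 3-SD screens (Theil–Sen,
  M-estimators) are out of scope, as are Bayesian causal-inference models
  of partial fusion.
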