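---
title: "Models and methods behind dstsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dstsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dstsim)
```

This vignette documents the models implemented in `dstsim`, the design
decisions taken where the deployed protocol leaves details open, the
calibration of the synthetic-participant generator, and the numerical
conventions used throughout. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The protocol engine

### Arithmetic task and staircase

The stress-condition arithmetic task draws problems `a ∘ b` with
`a, b ∈ [1, 99]`, integer solutions in `[1, 99]`, over the four basic
operations; division problems are only valid when they divide evenly. The
sampler first picks the operation uniformly from the allowed set, then an
operand pair uniformly from the exhaustively enumerated valid pairs for
that operation (4851 pairs for addition and subtraction, 473 for
multiplication and division). Constructive enumeration rather than
rejection sampling was chosen because the valid-pair sets differ in size
by an order of magnitude across operations; enumeration makes the
within-operation distribution exactly uniform and cheap to verify against
a brute-force oracle.

The time limit follows a transformed up-down staircase: 3 consecutive
correct answers shorten the limit by the adaptation fraction (10 %), 3
consecutive wrong-or-timeout trials lengthen it by the same fraction. The
triggering streak counter resets to zero when its rule fires — the rules
are interpreted as "a series of *k*", not as a sliding window, matching
how MIST-style transformed staircases are usually implemented. With equal
up and down run lengths the balance point satisfies `p³ = (1−p)³`, so a
participant whose probability of success increases continuously in the
limit is held near 50 % accuracy in the long run; the test suite verifies
this over 10⁴ trials against an independently coded Markov simulation.
The control condition's asymmetric 4-correct / 1-wrong rule moves the
balance point far toward easy, which is the protocol's intent.

Three interpretation decisions around the streak counters:

* **Timeout semantics.** "Incorrectly (or not at all)" is read as:
  timeouts count toward the easier streak together with wrong answers. A
  separate no-input counter backs the rescue rule and counts only trials
  with zero keypresses; any keypress (even a wrong answer) resets it.
* **Rescue scope.** The rescue rule (an easy addition after 5 silent
  trials) is described only for the stress condition and is therefore
  enabled only there by default; the flag `rescue_enabled` makes the
  choice explicit and configurable.
* **Rescue aftermath.** A pending rescue forces exactly one addition
  problem with single-digit operands, after which normal generation
  resumes and the no-input counter restarts at zero.

Further numerical conventions: adapted limits keep full float precision
(no rounding to display ticks); the limit is clamped to configurable
bounds, default `[0.5 s, 30 s]`, purely to keep degenerate simulations
(e.g. a perfect instant responder) numerically sane — the bounds are
logged with every session; the live percent-correct display shows 0
before the first trial and counts timeouts in its denominator; the task
stops at exactly 90 s of task clock and a problem in flight at the cutoff
is truncated without an outcome and excluded from the presented count.

### Keypad swapping and the speech task

After every limit-tightening in the stress condition, the next 4 tasks
get a fresh uniformly random non-identity permutation of the ten digit
keys (a new permutation per task; the deployed frequency is unstated, and
per-task resampling is the strongest reading of "swapped randomly"). The
control condition never permutes.

The speech task schedules 3 scenarios of 10 s preparation + 20 s
presentation. A speaker model supplies silent-gap intervals per
presentation window; each *maximal* gap of at least 1 s produces exactly
one reminder event, 1 s after the gap begins.

### Sessions, time and replay

Sessions run on a discrete-event clock in float seconds from session
start; there is no wall-clock dependence. Non-task stages (framing,
questionnaires) consume nominal durations scaled by a per-participant
pace multiplier, so total session durations vary realistically for the
duration-outlier exclusion filter. Each session uses a single seeded RNG,
the seed is recorded in the log header, and identical inputs replay to a
byte-identical JSON Lines log — this is asserted in the test suite, and
it is what makes logs citable artifacts.

## 2. The synthetic cohort

The generator produces data with the statistical structure the evaluation
pipeline assumes; it does not claim to reproduce human behavior beyond
that structure.

### Skill model

Solve times are log-normal per operation (defaults: median 1.6 s for
addition, 2.0 s subtraction, 2.8 s multiplication/division, log-SD 0.35 —
plausible magnitudes for simple mental arithmetic on a phone keypad,
chosen once and not tuned). The probability of a correct answer is a base
accuracy (0.95) attenuated by a logistic function of
`log(limit / solve time)`, which makes accuracy continuous and strictly
increasing in the limit — the premise of the staircase equilibrium. A
permuted keypad adds a motor penalty (0.8 s). A small per-trial no-input
probability (0.02) exercises the rescue machinery.

### Affect model and its calibration

Each outcome (two PANAS subscales on 1–5, four VAS scales on 0–100) is
generated at the subscale level: the baseline is a shifted gamma with the
configured mean and SD (right-skewed and floor-respecting, as affect
scores near the bottom of their range are), and each later timepoint adds
a latent normal change, clamped to the instrument range.

Clamping would bias the realized change moments away from the configured
ones, so the latent change mean and SD are *moment-matched* at profile
construction: a fixed common-random-numbers sample (2·10⁴ draws from an
internal RNG stream that does not touch the user's seed) is pushed
through the clamp and the latent parameters are adjusted by Nelder–Mead
until the realized change mean and SD equal the configured targets. This
is what makes "configured effect = generated effect" hold, which the
parameter-recovery and monotonicity properties in the test suite rely
on. The calibration is cached per parameter set.

PANAS targets are then *itemized*: each five-item subscale is set to the
integer item total nearest `5·target` and spread over the items in random
order, so the realized subscale mean is within 0.1 of the target and the
full item-level scoring path is exercised end to end. A scheme with
independent per-item latent normals was rejected because the extra
item-level variance inflates subscale and change SDs above their
configured values; the nearest-total scheme keeps the subscale-level
moments faithful at the cost of less realistic item-level covariance,
which nothing downstream consumes.

The default parameter set (`affect_defaults("table2_default")`) encodes
the published group-level summary of the study being emulated: the stress
arm's negative affect changes by +0.27 score points (SD 0.61) from a
1.57 (0.56) baseline, positive affect by +0.29 (0.61) from 3.08 (0.65);
the control arm's negative affect drifts −0.09 from 1.58 (0.58). The
control arm's change SD is not printed in the source tables; 0.61 (the
stress arm's value) is used as a realistic stand-in. VAS cell means are
chosen to reproduce the published group and time marginals (a strong rise
over the arithmetic task, partial recovery over the speech task, much
flatter in the control arm); within-cell SDs of ~18–22 points are
typical for affect VAS data.

### Dropout

Dropout is modeled as independent per-stage Bernoulli hazards at five
checkpoints (intro, math, intermediate, speech, post). The default
hazards are back-fitted: the four later-stage hazards are fixed at values
qualitatively matching the observed pattern (most stress-arm attrition
before the arithmetic task), and the intro hazard is solved analytically
so the product of survival probabilities equals the observed completion
fractions — 112/300 (stress) and 206/247 (control). Completion of a
simulated cohort is therefore binomial around those fractions by
construction, which the test suite checks at the original cohort sizes.

### What the generator does not emulate

No physiological stress response, no learning or fatigue within the
arithmetic task, no dependence of questionnaire answers on task
performance, no item-level response styles, and no informative dropout
(hazards do not depend on the participant's state). Consequently, passing
tests show that the *pipeline* is correct and calibrated for data with
the assumed structure — not that the behavior model reproduces human
latency or affect dynamics.

## 3. The statistical pipeline

The mixed-design (split-plot) ANOVA is fitted as a multivariate linear
model with `car::Anova` (repeated-measures `idesign`), which supplies the
univariate split-plot decomposition, Mauchly's sphericity test and the
Greenhouse–Geisser correction; with a two-level within factor, sphericity
holds trivially and ε is reported as exactly 1. Listwise deletion is
applied to participants missing a time level, and the excluded ids are
reported. Partial η² is computed as `SS_eff/(SS_eff + SS_err)`, which
equals `F·df₁/(F·df₁ + df₂)`. In the 2 × 2 design the interaction F
equals the squared pooled two-sample *t* on change scores; the suite
asserts this identity to 10⁻⁸ relative tolerance.

Post hoc group comparisons use Welch's *t* (unequal arm sizes, variance
heterogeneity), Bonferroni-adjusted within a family defined as the set of
post-baseline timepoint comparisons for one measure. Assumption checks
(Shapiro–Wilk, Levene) are advisory: they are reported and the ANOVA
proceeds regardless, relying on its robustness — the same policy as the
study being emulated. Constant samples are rejected as degenerate rather
than given a meaningless normality p value.

### Effect sizes: a deliberate ambiguity, kept visible

The published table labels its effect size d_z (change-score
standardization), but every printed value is numerically the *pooled
pre/post* variant `(m₂−m₁)/√((s₁²+s₂²)/2)` — e.g. 1.57 (0.56) → 1.84
(0.70) gives 0.426 pooled versus 0.443 as `0.27/0.61`. The package
implements both variants, records the variant with every value, and
defaults table reproduction to `pooled_prepost` because that is what
agrees with the published numbers. Neither variant is silently
"corrected"; the discrepancy is surfaced here and in the function
documentation. The two variants coincide exactly when pre and post SDs
are equal and the pre/post correlation is 0.5, a relation the test suite
checks numerically.

### Meta-analysis conventions

The two-step meta-analysis combines per-study standardized changes with
weights `wᵢ = 1/SD_Δ,ᵢ²` — the inverse of the change-score variance
*without* a sample-size factor — applied to absolute effect sizes. Both
conventions are forced by the published combined values: the positive-
affect study with change −0.01 is tabulated as d = 0.022, and the
combined values 0.667/0.119 only reproduce under `|d|` with
size-free weights. The combination is order-invariant and bounded by the
smallest and largest `|d|`.

## 4. Problem sizes used by the test suite

The suite verifies generator soundness on 10⁵ sampled problems with
exact pair counts against an exhaustive oracle; staircase equilibrium
over 10⁴ trials; null calibration of the pipeline's interaction test over
500 replicates at n = 30 per arm (a size at which the 2 × 2 interaction
test is exact, so calibration does not require the original cohort size);
and parameter recovery over 100 replicates at the original completer
sizes n = 103/181, using the questionnaire-only fast path
(`simulate_questionnaires()`), which is distributionally identical to the
engine path for questionnaire outcomes because task behavior does not
feed back into the affect model.

## 5. Known limitations

* The deployed application's rounding of adapted time limits, if any, is
  unknown; full float precision is kept.
* Whether the rescue rule exists in the control condition is not
  documented; it is off there by default but configurable.
* The "unrealistic procedure duration" exclusion threshold is
  unspecified in the source; the filter's window is configurable
  (default 2–30 min) and makes no claim to match the original.
* The I-PANAS-SF item wording bundled with the package is the published
  English form as a documented placeholder; the deployed study language
  is not modeled, and no psychometric claims attach to the fixture.
* Session-stage durations outside the timed tasks are nominal constants
  scaled by a pace multiplier, not a behavioral model.
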