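# dstsim

Simulation engine and statistical evaluation for a smartphone-delivered
acute psychosocial stress protocol — a "digital stress test" (DST) in the
TSST/MIST family — and its non-stressful control condition (C-DST).

The package is aimed at researchers who want to study the *protocol* (its
adaptive difficulty dynamics, dropout behavior, and the power and
calibration of its evaluation statistics) without a browser runtime or
human participants: everything is headless, seeded and replayable.

## What it implements

**Protocol engine.** The stressful arithmetic task presents problems
`a ∘ b` with operands and integer solutions in [1, 99] over
`+, −, ×, ÷`, under a transformed up-down staircase on the per-trial time
limit *L*:

* start at *L* = 3 s; after 3 consecutive correct answers, *L* ← 0.9·*L*
  and the digit keypad is randomly permuted for the next 4 tasks;
* after 3 consecutive wrong-or-timeout trials, *L* ← 1.1·*L*;
* after 5 consecutive trials with no input at all, a "rescue" easy
  addition is inserted;
* the task stops at 90 s; a live percent-correct score is displayed
  against a fabricated 75 % comparison-group average.

Because the up and down run lengths are equal, the staircase balances where
`p³ = (1−p)³`, i.e. holds a responsive participant near 50 % accuracy. The
control variant is addition-only at 5 s with an asymmetric 4-correct /
1-wrong rule (and no swap, comparison or rescue), so accuracy stays high.
A free-speech task (3 scenarios, 10 s preparation + 20 s presentation,
silence reminder after 1 s without voice input) and the questionnaire
schedule (I-PANAS-SF at 2 timepoints, four 0–100 VAS scales at 3
timepoints) complete the session, which is logged as an ordered,
replayable JSONL event stream.

**Synthetic participants.** Skill (log-normal solve times, logistic
accuracy attenuation under time pressure, keypad-swap motor penalty),
affect outcomes with calibrated group × time structure, stage-wise dropout
hazards back-fitted to the observed completion fractions, and whole
two-arm cohorts.

**Statistics.** Shapiro–Wilk/Levene checks, split-plot (mixed-design)
ANOVA with Mauchly's test and Greenhouse–Geisser correction, partial
η² = F·df₁/(F·df₁ + df₂), Bonferroni-adjusted Welch post hocs, paired
*t* tests, two Cohen's *d* variants for pre/post change
(d_z = Δm/SD_Δ and the pooled variant d = (m₂−m₁)/√((s₁²+s₂²)/2)),
and a two-step inverse-variance meta-analysis combining per-study effects
with weights wᵢ = 1/SD_Δ,ᵢ² on |dᵢ|.

## Worked example

```r
library(dstsim)

spec <- cohort_spec(n_stress = 103, n_control = 181, seed = 1, dropout = "none")
res  <- simulate_cohort(spec)
rep  <- evaluate_study(res$questionnaires, measures = "panas_na")
print(rep)
```

```
<dst_report: 284 participants, groups: control, stress>

== panas_na ==
group          F(1, 282) = 17.519, p = 3.805e-05, eta_p^2 = 0.058
time           F(1, 282) = 0.706, p = 0.4014, eta_p^2 = 0.002
group_by_time  F(1, 282) = 46.708, p = 5.085e-11, eta_p^2 = 0.142
  post hoc post         control vs stress: t = -5.655, p_bonf = 6.984e-08
  control pre/post d: -0.257 (pooled), -0.254 (change-SD)
  stress pre/post d: 0.435 (pooled), 0.598 (change-SD)
```

The synthetic stress arm's negative affect rises from baseline to
post-test while the control arm's drifts slightly down, producing the
group × time interaction the design is built to detect; the stress arm's
pooled pre/post *d* (here 0.435, one random cohort at the default
configured change of 0.27 score points with SD 0.61) fluctuates around
the configured standardized change.

The meta-analytic comparison runs from the bundled study-summary table:

```r
m <- meta_analyze(read_study_summaries(), "NA")
sprintf("combined TSST NA effect: %.3f; DST NA effect: %.3f",
        m$combined$combined_d, m$dst_d)
#> "combined TSST NA effect: 0.671; DST NA effect: 0.426"
```

A shell interface wrapping the same functions lives in `inst/cli/dst.R`
(subcommands `simulate`, `evaluate`, `meta`).

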