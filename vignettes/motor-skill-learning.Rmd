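---
title: "Quantifying motor-skill learning under fatigue: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor-skill learning under fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorskill)
```

This vignette is the package's own account of the science it implements:
the skill measure, the robust learning-rate estimator, the permutation
inference, the fatigue quantification, the synthetic-data generator, and
the design decisions taken where the methodology was genuinely open.

## The task and the skill measure

In the sequential isometric pinch task, a subject modulates pinch force
to steer a cursor (a logarithmic transduction of force,
`x = k ln(1 + F/f0)`) through five force windows — gates 1–4 and an end
target — in a fixed order. The strongest gate tops out at 40 % of the
subject's maximal voluntary contraction (MVC), so the task remains
executable even after a fatiguing contraction. A trial is an **error** if
any of the five targets is under- or overshot; the block **error rate**
is the fraction of error trials, and the block **movement time** is the
per-trial duration from movement onset to the end gate, aggregated over
the block.

Performance involves a speed–accuracy trade-off: one can be fast and
sloppy or slow and accurate. The skill score collapses the two into one
number,

$$a \;=\; \frac{1 - ER}{ER\,(\ln MT)^{b}}, \qquad b = 5.424,$$

with $MT$ in seconds and $b$ a constant pre-calibrated for this task
family. The score increases when errors fall at constant speed or when
speed rises at constant accuracy, and `skill_measure()` is strictly
decreasing in both arguments (for $MT > 1$ s, where the logarithm is
positive).

Two numerical choices (`adjust_error_rate()`):

* **Boundary error rates.** The formula is undefined at $ER \in \{0,1\}$.
  Rates are clamped to $[0.5/n,\, 1 - 0.5/n]$ for an $n$-trial block — a
  standard continuity correction that keeps the score finite and
  preserves monotonicity. An error-free 30-trial block therefore scores
  as if $ER = 1/60$.
* **Block movement time.** The aggregate is the arithmetic mean of trial
  movement times by default; a median option
  (`summarize_blocks(mt_aggregate = "median")`) is exposed because the
  choice is not dictated by the method.

The unit requirement $MT > 1$ s is structural: the non-integer exponent
$b$ needs $\ln MT > 0$. The generator keeps all movement times above
1.2 s, and `skill_measure()` refuses shorter times rather than returning
complex garbage.

## Learning rate: pooled robust regression

Skill grows roughly linearly over the four blocks of a session, so the
**learning rate** is the slope of a linear fit of skill on block number,
estimated separately per group and day. Two estimator decisions:

* **Robustness.** The fit is by iteratively reweighted least squares
  (`irls_fit()`): starting from OLS, residuals are standardised by the
  MAD-based scale `median(|r|)/0.6745` and converted to Tukey bisquare
  weights (tuning 4.685; Huber 1.345 selectable), iterating to a 1e-8
  coefficient tolerance, at most 100 iterations. These are the
  conventional defaults of robust-fit routines in numerical computing
  environments. Skill scores are right-skewed (see below), and single
  wild blocks would otherwise leverage the slope.
* **Pooling.** One regression per group-day over *all* subject-by-block
  points (`pooling = "pooled"`), not an average of per-subject slopes.
  The pooled fit weights every block observation equally and is the
  package default; `pooling = "per_subject"` is available as a
  sensitivity analysis. With two groups the two conventions can differ
  when subjects vary strongly in level, which is why both exist.

When a design has only two blocks (e.g. the untrained hand measured
before and after training), the learning measure is the per-subject
block 2 − block 1 skill difference (`transfer_delta()`). The pooled OLS
slope of a two-block series equals the group mean of these differences
exactly, which is why the transfer comparison in the pipeline uses the
plain estimator.

## Permutation inference

Learning-rate differences between groups are tested by subject-level
permutation (`permutation_slope_test()`): under the null of no group
difference, group labels are exchangeable *across subjects*, so subjects
are reassigned to groups of the original sizes — a subject's whole block
series moves as one unit, preserving within-subject correlation — and
the slope difference is recomputed per reassignment (default 10,000).

* **Counting rule.** `p = #{ |Δ*| ≥ |Δ_obs| } / n_perm`, ties counted as
  exceeding. The default is two-sided on the absolute difference; signed
  one-sided alternatives are available, as is a `(k+1)/(n+1)` small-sample
  correction flag (off by default, so the reported number is the plain
  resampled proportion).
* **Exactness.** For small groups `exhaustive = TRUE` enumerates every
  distinct reassignment (refused above `choose(20, 10) = 184756`), making
  the p-value exact, deterministic, and invariant to subject labelling.
* **Statistic inside the loop.** The observed statistic uses the robust
  estimator, and by default so does every resample. A plain-OLS option
  (`estimator = "ols"`, roughly 40× faster) exists for two reasons: speed
  at large `n_perm`, and a genuine statistical phenomenon — when the two
  groups form nearly noiseless, widely separated clusters of subject
  slopes, a redescending estimator fitted to a mixed resample latches
  onto the majority cluster, so extreme resampled differences become
  common and the test loses power even though the observed separation is
  enormous. The permutation test remains exact either way (any statistic
  yields a valid level); the choice affects power only. At the group
  sizes of the designs shipped here (18–20 per group) the robust default
  does not saturate.
* **Across-day comparisons.** How to resample for a within-group
  day-1-vs-day-2 contrast is not determined by the between-group
  procedure. This package uses within-subject day-label exchanges
  (sign-flip resampling, `paired_day_slope_test()`): each resample
  independently swaps a subject's day-1 and day-2 series. This is the
  package's design choice for the paired design and is recorded in the
  result's `method` field.

## Classical tests

Movement time and error rate are compared by a mixed block × group
repeated-measures ANOVA (`mixed_anova()`). Sums of squares come from the
balanced two-way mixed decomposition (group tested against
subjects-within-group; block and block × group against the within-subject
residual). Sphericity of the 4-level within factor is handled by the
Greenhouse–Geisser epsilon, estimated from the pooled within-group
covariance matrix of the repeated measures,
$\hat\varepsilon = \mathrm{tr}(CSC)^2 / \big[(k-1)\,\mathrm{tr}((CSC)^2)\big]$,
clamped to $[1/(k-1), 1]$; corrected p-values scale both degrees of
freedom by $\hat\varepsilon$. Designs with missing cells are refused
rather than imputed. Supporting utilities follow the standard workflow:
`normality_gate()` (Shapiro–Wilk screen with natural-log fallback for
positive skewed measures), `two_sample_t()` (pooled variance, with the
conventions t = 0 for identical constant samples and an error for
constant samples with unequal means), and `bonferroni_adjust()`.

## Fatigue quantification

Muscle fatigue is defined mechanically: degradation of maximal force
output after voluntary exertion. From a force trace (`force_trace()`,
regular samples in Newton):

* `mvc_from_trace()` — maximum of the moving-average-smoothed trace of a
  short maximal effort. Smoothing window 0.2 s by default.
* `gate2_threshold()` — the stopping threshold for the fatigue
  induction: the upper force limit of the strongest gate, 40 % of MVC by
  default.
* `time_to_fatigue()` — first moment the smoothed force stays below the
  threshold for at least `hold = 0.5` s; shorter dips are treated as
  transducer noise. Returns `NA` when never reached.
* `fatigue_decrement()` — `1 − mvc_post/mvc_pre`; stopping at 40 % of
  MVC corresponds to a 0.60 decrement.

The smoothing window and hold are this package's choices (the
quantification is otherwise underdetermined); both were set to reject
realistic transducer noise while biasing the crossing time by less than
one smoothing window, and both are arguments, not constants. Surface-EMG
monitoring of the contraction is out of scope; traces are force-only.

## The synthetic-data generator

The generator exists so that every analysis stage is testable end to end
without human data. It operates at two levels.

**Skill level** (`simulate_skill_table()`): one score per subject per
block, `baseline + slope·block + N(0, σ²)`. This is the generator used
to study the estimator itself — slope recovery, permutation calibration
and power — because its truth is directly the quantity the estimator
targets. Defaults σ = 0.05 with slopes of order 0.04–0.17 per block,
matching the magnitudes typical of this task family.

**Trial level** (`simulate_pinch_experiment()` with `sim_config()`):
the full generative chain.

* Each subject carries a Gaussian random skill intercept
  (`subject_sd = 0.10`); each block adds noise (`block_sd = 0.05`).
* The block's target skill is `baseline + carryover·(previous days'
  gains) + slope_d·block`; day-to-day carryover defaults to 0.8 of the
  accumulated gain.
* Movement times are shifted-lognormal, floored at 1.2 s, with the block
  location decaying multiplicatively (start 4.5 s, decay 0.97 per
  block) and `sdlog = 0.15`, mean-corrected so the block expectation
  equals the location used in the error model.
* The block error probability is the *inverse* of the skill formula at
  the block's target skill and expected movement time.
* Mechanistically, each gate's executed force is the target force,
  multiplicatively biased upward on fatigued days by
  `β(1 − f/f_max)` (β = 0.08) — largest at the weakest targets, the
  signature of post-contraction force underestimation — plus Gaussian
  noise proportional to the target force. The noise coefficient is
  calibrated per block (by `uniroot`) so that the probability of missing
  any gate equals the skill-model error probability. Outcomes are
  classified against the gate windows (±12 % of the target force, a
  config-exposed default; the strongest gate's upper limit is exactly
  0.40 of MVC).
* A single master seed spawns per-subject substreams, so adding a
  subject or group never perturbs existing subjects' data and equal
  seeds give byte-identical tables.

Two honest limitations of the trial-level path. First, with 30 trials a
block's empirical error rate is granular (multiples of 1/30, boundary
clamped at 1/60), and the skill transform is convex in it; at high skill
(low error rates) this compresses the measured skill scale, so pooled
fitted slopes on trial-level data run some 5–25 % below the generating
skill-scale slope, increasingly so at higher skill. This is a property
of the measure at finite block length — real 30-trial data has it too —
which is why estimator validation uses the skill-level generator and why
the trial-level presets are described as plausible presets rather than
ground truth. Second, the generator draws trials independently given the
block; it does not emulate serial autocorrelation, learning within a
block, or strategic slowing after errors.

The sequence-task generator (`simulate_sequence_experiment()`) emulates
the 10-element key-press control task: per-press shifted-lognormal times
(start 0.5 s, decaying 0.93 per block), binomial wrong presses with a
per-press probability of 0.03 declining by 0.9 per block, and — because
fatigue showed no effect on this cognitively demanding but
force-undemanding task — identical parameters for both groups, so the
generator's null structure mirrors that finding. Movement time is
defined over the ten correct presses; wrong presses pause the sequence
but add no time.

**MVC model:** sustained maximal contraction declines exponentially,
`F(t) = MVC·e^{-λt}` with λ = ln(2.5)/68.91 ≈ 0.0133 s⁻¹ by default, so
the force reaches the 40 %-of-MVC stopping threshold in ≈ 69 s and the
resulting decrement is 0.60; the matched control contraction is flat at
5 % of MVC.

## Pipeline and problem sizes

`experiment_spec()`/`run_experiment()` orchestrate the four shipped
designs (two-group two-day fatigue study, 20/18 subjects; intermanual
transfer, 10/10, one day plus left-hand pre/post blocks of 15 trials;
three-group two-day study, 10/15/15, with three pairwise comparisons per
day and three within-group day tests; and the sequence-task control,
9/9, ANOVAs only). Bundles carry provenance (an FNV-1a hash of all
analysis-relevant spec fields, the seed, the package version), serialise
losslessly to JSON, and render to a report whose per-comparison
histogram bins always sum to the number of resamples.

The test suite validates each stage against independent oracles
(closed-form OLS, full permutation enumeration, brute-force ANOVA
decomposition, closed-form crossing times) and runs Monte-Carlo studies
at deliberately moderate sizes — 400 null replicates at 500 resamples
for type-I calibration, 200 seeds for slope recovery, 100 replicates for
separation power — chosen to keep the whole suite comfortably
re-runnable on one CPU while leaving the binomial uncertainty of each
check well inside its acceptance band. The calibration band
[0.03, 0.08] at α = 0.05, for instance, is about ±3 binomial standard
errors at 400 replicates.

## Known limitations

* The skill constant b = 5.424 is task-specific; applying the measure to
  other tasks requires recalibration, which the package does not do.
* Learning curves are modelled as linear in block; saturating
  (exponential/power-law) models and mixed-effects growth models are out
  of scope.
* The permutation machinery assumes complete block series per subject;
  designs with dropout need explicit handling upstream.
* Force traces are analysed for MVC and threshold crossings only — no
  EMG processing, and no decomposition of central versus peripheral
  fatigue.
* The OSF-style deposited datasets of real experiments can be loaded
  through the generic CSV readers plus a column-mapping step, but no
  downloader is shipped and nothing here depends on real data.
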