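---
title: "Measuring motor vigour and movement fusion in sequential reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring motor vigour and movement fusion in sequential reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqreach)
```

## The measurement model

A trial is one continuous sequence of eight reaching movements through a
central via target: out and back to each of four outer targets (10 cm on the
vertical axis, 5 cm at 126° separation), ending on the via target. Three
per-trial quantities summarise performance:

- **Movement time (MT)**: time from exiting the 2 × 2 cm start box to first
  entry into the final target.
- **Peak velocity**: the speed profile is the Euclidean norm of the first
  difference of the 110 Hz cursor positions divided by the time step,
  smoothed with a Gaussian kernel of σ = 2 samples (truncated at ±4σ,
  reflective boundaries). The profile is divided into 8 segments — from the
  sample where the cursor exits one target's 0.5 cm disc to the sample where
  it exits the next (the final segment ends at first entry into the final
  target) — and `v_max` is the per-segment maximum, averaged over the trial.
- **Fusion index (FI)**: for each of the 7 transitions,
  `FI = 1 − (mean(v_max1, v_max2) − v_min) / mean(v_max1, v_max2)`, where
  `v_min` is the minimum smoothed speed in the open interval between the two
  adjacent peak samples. FI is the trough as a fraction of the mean adjacent
  peak: 0 is a complete stop, 1 a fully fused transition. The trial FI sum
  is therefore at most 7.

Design choices where the measurement was underdetermined: target entry/exit
use the point-cursor convention (cursor centre against the 0.5 cm target
radius); FI is clamped to [0, 1] because a trough can numerically exceed the
mean of the peaks (a clamp counter is kept); the `v_min` search window is
the open inter-peak interval rather than a spatial window around the via
point; speed uses first differences rather than central differences — with
σ = 2 smoothing the difference is far below measurement noise. MT is
anchored at start-box exit, while the separate reaction time uses the 2 cm
displacement rule, keeping the two onset definitions distinct.

## The synthetic cohort

The generator exists so that every stage of the pipeline can be validated
against known ground truth. Each participant carries a baseline segment peak
speed (`vigour0`, cm/s), a per-trial vigour learning slope, a baseline
transition trough fraction (`fusion0`) with its own slope, and a positional
noise scale. A trial's path follows the target polyline with one speed bump
per movement: a quintic-smoothstep rise from the entry speed to the trial's
peak speed and a symmetric fall. This family has the property the analysis
assumes — a unimodal, bell-shaped speed profile per segment — and, because
the smoothstep has zero first and second derivative at its endpoints, the
profile is C² with flat extrema, which keeps the measured peaks and troughs
close to their programmed values after smoothing and differencing.

Two discretisation details matter at 110 Hz. First, segment durations are
rounded to even multiples of the sampling interval (with peak speeds
re-solved), so direction reversals at targets and speed peaks land exactly
on sample instants; otherwise the first-difference speed is attenuated
whenever a sampling interval straddles a turn. Second, because the analysis
measures fusion on the *smoothed* profile, the junction speeds are
calibrated by a short fixed-point iteration against the package's own
kinematic measurement of the noise-free path; the programmed trough
fraction is then the fraction the pipeline recovers (to well within 0.01
across the usable range; the oracle-equivalence test checks 200 trials at a
0.02 tolerance). A fully fused reference trial (fraction 1) is built
separately as a constant-speed traversal whose cruise speed is chosen from
the grid-commensurate family `v = 5 cm/(m·Δt)`, making the measured speed
exactly constant across transitions and every FI exactly 1.

At a trough fraction of zero the cursor halts inside each target for at
least `dwell_floor` (0.15 s by default); for positive fractions the dwell
time shrinks implicitly as the pass-through speed rises. The profile-driven
trough fraction is clamped at 0.95; only the explicit `trough_fraction`
override reaches 1.

Cohort defaults are the study conditions this design targets: 110 Hz
sampling; Baseline 10 / Training 200 / two post phases of 20 trials (25 on
day 7); dual-task flags every 10th Training trial and every 5th trial
elsewhere; baseline vigour ~21 cm/s, which yields a baseline mean MT of
about 5.3 s over the 60 cm path, matching the scale reported for this
paradigm. Group learning slopes follow the qualitative pattern of interest —
rewarded-placebo fastest vigour growth (~0.024 cm/s per trial), rewarded-
haloperidol flat, unrewarded groups intermediate; fusion improving in all
groups but least in high-WM haloperidol participants — reading the reported
group slopes as per-100-trials coefficients (their units are not stated).
Positional noise defaults to 0.03 cm, the scale of electromagnetic tracker
jitter. Each participant draws an independent random stream keyed by group
and within-group position, so growing a cohort never reshuffles existing
participants.

What the generator does *not* emulate: biomechanical arm dynamics, curved
or corrective paths, missed targets and repeated trials, reaction-time
variability, or the force-sensor signal of the dual task (dual-task trials
are only flagged for removal). Passing tests therefore demonstrate the
*pipeline's* correctness and calibration on data satisfying its
assumptions, not robustness to every idiosyncrasy of real cursor data. One
known consequence of noise: differentiated positional noise puts a floor
under measured troughs, so noisy low-fusion trials read slightly higher FI
than programmed; this biases all groups alike and leaves slopes usable.

## Closed-loop reward

Each trial's MT is ranked against the previous 20 trials (the current trial
is not inserted before ranking; ties favour the participant). The rank
percentile — 100 × (buffered MTs strictly slower)/20 — maps to 0–5 points
through the band edges 20/40/60/80/90. The printed "top three / bottom
three" description of the extreme bands conflicts with those percentile
edges (top 3 of 20 is ≥85%); the percentile bands are taken as normative
and a `rule = "topbottom3"` switch implements the alternative reading. At
block boundaries the buffer is seeded with the last 20 trials of the
previous block; with fewer than 20 available, scoring is flagged as
warm-up. Because the comparison set tracks recent performance, steady
improvement does not saturate the payout — the criterion adapts.

## Inference

**Trial-level LMM.** `dv ~ Reward*Drug*WM*Trial + (Trial | Participant)`,
REML, Satterthwaite degrees of freedom, treatment coding with NoReward,
haloperidol and low WM as references. Trial number is divided by 100 before
fitting — purely numerical conditioning; with raw trial numbers 1:180 the
random-slope covariance is ill-scaled and the optimizer stalls. The
coefficient table is thus in dv-units per 100 trials while
`marginal_slopes()` converts to per-trial units. If the maximal model fails
to converge the random slope is dropped and the fit is flagged
(`fallback = "intercept_only"`), never silently.

**Marginal slopes and contrasts.** A group's slope is the linear
combination of fixed effects obtained from the difference of design rows at
consecutive trial numbers, averaging factors outside the grouping with
equal weights; its SE is the corresponding quadratic form of the
coefficient covariance. The unit tests cross-check this construction
against per-group OLS on noise-free data and against an independent
marginal-trends routine. Pairwise slope comparisons use
`z = (β1 − β2)/√(SE1² + SE2²)` with Bonferroni correction over the pairs;
when only printed 95% CIs are available, `ci_to_se()` assumes normal
intervals (SE = width/3.92).

**Permutation trial windows.** Per analysis trial, a Welch t statistic
between two groups of participant series; the null is built by shuffling
participant group labels (default 5,000 shuffles — the count is not
prescribed by the design, so it is configurable) and a trial is significant
when observed |t| exceeds the 1 − α quantile of its own permutation
distribution. The identity permutation is included in the null set, which
keeps the per-trial level at or below α at finite permutation counts.
Maximal runs of significant trials are reported as windows; no across-trial
cluster correction is applied, matching the per-trial thresholding this
design reports.

**Post assessments.** Trial distributions in the short post phases are
typically non-normal (one-sample Kolmogorov–Smirnov checks are reported),
so per-participant medians per Timepoint enter a mixed ANOVA (Reward, Drug,
WM between; Timepoint within, via `aov()` error strata). Follow-up Wilcoxon
rank-sum tests compare the post-Rew minus post-NoRew difference between the
four one-factor-apart group pairings (the pairing set is not fully
specified by the design; all six pairs are available via an argument), with
FDR correction and Cohen's d.

**Positive control.** The Go/NoGo learner is a two-learning-rate
Rescorla–Wagner model with a Go bias — win and loss learning rates are
separate precisely so a haloperidol-like asymmetry (better learning from
wins, worse from losses) can be injected. Stimulus win probabilities
default to 0.8/0.8 for reward runes and 0.2/0.2 for loss runes; the real
mapping is not published, so they are configurable. Response accuracy
(Learn+ = %Go on reward stimuli, Learn− = %No-Go on loss stimuli) feeds a
Drug × Feedback mixed ANOVA run separately for low- and high-WM
participants, with WM classes from a median split of the verbal-memory
score over array lengths 7–9 (ties at the median go high; the reported
class sizes imply strictly-below-median is "low").

## Numerical choices and degenerate inputs

Non-uniform sampling beyond 1 ns is rejected, naming the offending gap. A
target never entered, or entered out of order, aborts segmentation naming
the first violated target. Empty segments, non-positive peak speeds,
non-positive MTs, zero slope SEs and single-participant groups raise
errors; fewer than 100 permutations warns. FI clamping events are counted
per trial. Exclusion filters are idempotent and report counts that conserve
the input.

## Problem sizes used by the test suite

The suite validates calibration at the scales a desk re-analysis can
afford: oracle equivalence on 200 noise-free trials; permutation type-I
error over 200 exchangeable-null replicates (12 participants/group, 30
trials, 200 shuffles); slope-sign recovery over 100 simulated cohorts at 24
participants per group × 180 trials (using the metrics-level generator, so
the hundred mixed models dominate the runtime); window localisation of a
1-SD shift in trials 170–180 over 100 seeds. The full trajectory-level
pipeline runs end to end in the demo profile (2 participants/group, day 1);
the full-scale profile (23/group, days 1, 2 and 7, 5,000 permutations) is
available behind `run_config(profile = "full")`.

## Known limitations

- The generator's straight-line paths make the fully fused limit depend on
  the grid-alignment construction; real fused reaches curve around targets
  instead.
- Measured FI under positional noise is upward-biased at low fusion (noise
  floor in the trough), so absolute FI levels should be compared only
  within a noise setting.
- The LMM's random-effects structure is fixed to intercept + trial slope;
  richer structures (e.g. phase-specific slopes) are out of scope.
- Reported group slopes are interpreted per 100 trials when seeding the
  generator; if they were per trial, only the generator's effect-size
  defaults change, not any measurement or inference code.
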