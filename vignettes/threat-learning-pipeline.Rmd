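---
title: "Methods: lap-based behavior and prediction-error coding analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lap-based behavior and prediction-error coding analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazepe)
```

This vignette is the package's account of what each analysis computes, which
assumptions it rests on, and where genuinely open design choices were
resolved.

## Task geometry and lap segmentation

The maze is a 75 × 75 cm square with two 20 × 20 cm reward sites at opposite
corners and two 8 × 20 cm threat sites at the remaining corners
(`maze_geometry()`). Each path between the reward sites passes through
exactly one threat site, so a lap's path is identified with the threat ROI
it crosses.

ROI membership is *half-open* (`xmin <= x < xmax`, likewise in y), so a
point on a shared edge belongs to at most one ROI, and an entry is stamped
with the first tracked sample inside the rectangle, an exit with the first
sample outside. `detect_roi_events()` is a pure per-sample scan; the
tolerance for tracking jitter at ROI borders lives in a separate step,
`merge_roi_reentries()`, which folds an exit followed by a re-entry into the
same ROI within 2 s (configurable) into one visit, provided no other ROI was
visited in between. Keeping the scan pure makes it directly checkable
against a brute-force point-in-rectangle oracle.

`segment_laps()` walks the merged event list: a *full* lap exits one reward
site, passes a threat site, and enters the other reward site; a *half* lap
returns to the starting reward site; an excursion that never reaches a
threat site is no lap at all. Air-puff and LED log entries must match a
threat-site entry within ±500 ms (puffs are triggered 100 ms after entry);
an orphan puff is an error, not a silent drop. If an excursion visits more
than one threat ROI — possible with erratic trajectories, impossible for the
generator — the lap is attributed to the first and a warning is raised.

## Speed, expectation, and latencies

Instantaneous speed is the first-order finite difference of position with
no smoothing; the 500-ms averaging windows (approach: `[t_entry − 0.5,
t_entry)`; reaction: `[t_entry, t_entry + 0.5)`) already suppress
sample-to-sample jitter, and smoothing would leak post-entry dynamics into
the pre-entry window. A lap whose window is not fully covered by the
recording, or contains fewer than two speed samples, is flagged invalid and
excluded rather than padded.

The expectation label is a per-session median split of approach speed:
*slow* laps are strictly below the session median, *fast* laps at or above
it, so ties go to fast and "slow" remains strictly sub-median. At least four
laps with valid approach speed are required; if every speed is identical all
laps are fast and a warning is logged. Fast + threat and slow + omission are
*surprising*; slow + threat and fast + omission are *expected*. Two open
choices were resolved as follows: the split is computed per session (not
pooled across stages), and half laps participate in both the choice
denominator and the speed analyses — the first follows the per-session
definition of the median, the second keeps the speed sample as large as
possible and is documented here as an assumption.

## Choice history

Laps are concatenated across the five probabilistic sessions in order, with
no reset of the trailing window at session boundaries. For each path, the
trailing threat-probability estimate at lap *i* with window k is the mean of
outcomes over the most recent k *visits to that path* strictly before lap
*i* (undefined until k visits have occurred); per-path windows follow from
threat probability being a path property. The Pearson correlation between
choice code (1 = high-threat path) and the estimate, over laps where the
estimate is defined, gets a two-sided p-value from the standard t
transformation. A mouse counts as significant for a path when any
k ∈ 1..50 gives p < 0.05; no multiple-comparison correction is applied
across k, matching the any-window criterion this analysis is defined with —
the type-I cost of that rule is itself measured (see below). Post-threat
switching discards sessions with fewer than two qualifying laps and mice
without usable data in every session.

## Event-aligned calcium analysis

Traces (20 Hz) are aligned to threat-site entry in a −1 s … +2 s window and
averaged into 30 half-open 100-ms bins; bin 11 is the first post-entry bin
and covers entry up to puff onset. Alignment uses timestamps only — calcium
(20 Hz) and tracking (30 Hz) clocks are never resampled onto each other.
For each lap type the binned activity is first averaged across laps and
then z-scored with the mean and SD of the first 10 (pre-entry) bins of the
averaged trace; normalization is per lap type, and a zero-variance baseline
marks that cell × type undefined rather than imputed. The response
magnitude is the mean z over bins 11–15. Outcome responders use a strict
`> 2` threshold; symmetric decreases (`< −2`) are reported separately — the
analysis defines only the increase threshold, so symmetry is an assumption
made explicit here. Differential activity subtracts expected from
surprising magnitudes per outcome type, and the ±2 thresholds yield the
seven-way classification (Up–Up, Up–Down, Down–Up, Down–Down, Threat-only,
Omission-only, none), with signed-PE = {Up–Down, Down–Up} and unsigned-PE =
{Up–Up, Down–Down}. Category proportions carry exact Clopper–Pearson
limits, and the between-group comparison tests one group's count against
the other group's proportion as the null rate.

A variant that z-scores each lap by its own baseline before averaging is
available for sensitivity analysis (`lap_type_average_z(..., per_lap =
TRUE)`) but is deliberately not the default: the lap-averaged z follows the
order of operations the analysis is defined with.

## Statistical toolbox

`mixed_anova()` implements the univariate split-plot decomposition for
designs with ≤ 1 between-subject factor crossed with ≤ 2 within-subject
factors — every design the analyses use (one-way RM; group × session;
group × path × session). The subject × cell matrix is projected onto
orthonormal within-subject contrasts; each stratum tests Type-III
hypotheses under sum-to-zero coding, so unequal group sizes are handled as
standard mixed-ANOVA software handles them. Sphericity is assessed per
within stratum with Mauchly's test (Box's chi-square approximation with the
second-order term); when its p-value falls below 0.05 — the conventional
trigger, chosen here because the analyses' definition does not state one —
the Greenhouse–Geisser epsilon, ε = tr(Σ)² / (d·tr(Σ²)) on the
contrast-projected error covariance, multiplies both degrees of freedom.
ε is clamped to [1/d, 1] and corrected dfs never exceed uncorrected ones.
Tukey's studentized-range follow-up uses the RM error term. The 2×2
chi-square is uncorrected by default (a continuity-correction flag exists):
at the cohort sizes involved the uncorrected statistic is the conventional
choice. Cross-checks against independent implementations (`aov` strata,
`car::Anova` Type-III tables, `stats::mauchly.test`) live in the test
suite.

## The synthetic generator: what it emulates, and what it does not

The agent (`simulate_agent()`) is a Rescorla–Wagner learner with softmax
choice over negated per-path threat values: PE = outcome − V(path),
V ← V + αPE (α may differ by PE sign), P(high-threat path) =
1/(1 + exp(−β(V_lt − V_ht))). Approach speed is `base − slope·V + noise`
and reaction speed `base_r + gain·PE + noise`, planting the
expectation–speed and surprise–reaction links the analyses are meant to
detect. It is a test harness, not a claim about mice.

Defaults (set once, for realism at the study's scale): α = 0.1, so learning
spreads over a few 60-lap sessions rather than saturating within one;
β = 2, giving ~73% asymptotic adaptive choice, in the range of the printed
learning curves; base/slope/noise = 30/20/3 cm/s, giving ~15 vs ~25 cm/s
approach speeds on learned paths with lap-to-lap noise small against the
path difference; 60 laps/session (behavioral sessions stopped at 60 laps);
dwell 2 s at reward sites. `switch_override` mode is the opsin-like
phenotype: forced alternation after every threat and a fair coin flip
otherwise — it never integrates value, keeping adaptive choice near 50%
and the stay-after-threat probability on the low-threat path at zero. (A
variant that still learns on non-threat laps drifts toward the low-threat
path, contradicting the phenotype this mode exists to emulate.)

`simulate_tracking()` realizes laps as piecewise-linear corridor
trajectories sampled at 30 Hz, with the approach leg at the lap's scheduled
approach speed and everything after entry at the reaction speed; boundary
crossings are computed analytically, so re-segmentation reproduces the
planted lap structure exactly and recovered approach speeds match scheduled
ones to machine precision. `simulate_calcium()` adds double-exponential
GCaMP6f-like transients (rise 50 ms, decay 500 ms, literature-typical; only
relative amplitudes matter after z-normalization) at threat-site entries on
Gaussian baseline noise: outcome cells fire on their path's threat laps
(scaled by an LED gain on LED laps for ChrimsonR-like cohorts), signed-PE
cells scale with PE (dips for negative PE), unsigned-PE cells with |PE|,
expectation cells ramp up over the final second in proportion to V.

The generator does not emulate: photon/indicator noise structure
(correlated, non-Gaussian), neuropil contamination or extraction artifacts,
drift and bleaching, trajectory variability off the corridor midlines,
session-boundary non-stationarity, or cell–cell correlations. Passing tests
therefore demonstrate that the analysis code computes what it claims on
data whose generative structure is known — not that the biological
conclusions would replicate on raw recordings.

## The planted-truth probe

`simulate_pe_probe()` is the validation condition for the PE classifier:
one 240-lap session with 50/50 threat probability on both paths and a
fast-updating agent (α = 0.5, values started at 0.5). Two properties make
it the right probe. First, balanced outcomes with fast updating maximize
lap-by-lap PE fluctuation and keep expected-outcome PEs near zero, so the
planted contrast is concentrated where the classifier looks. Second, the
value-driven speed variation (±~6 cm/s) dominates lap noise (±3 cm/s), so
the median-split expectation labels are mostly correct — the probe tests
the neural pipeline, not the behavioral inference. Under the study's 75/25
contingency with a strong low-threat preference, rare high-threat-path
omissions are diluted among low-threat-path laps in the slow half of the
session median split, and the omission-side differential shrinks toward the
±2 threshold; that ceiling is a property of the condition (choice
imbalance), not of the classifier, and is why the probe balances its
contingencies. At transient SNR 4 (amplitude = 4 baseline-noise SDs per
lap) and ≥ 15 laps per lap type, the suite requires seed-averaged
sensitivity and specificity ≥ 0.8 for planted signed-PE cells.

## Numerical choices and degenerate inputs

- Half-open bins and rectangles everywhere; no sample or point can be
  counted twice.
- Median-split ties go to "fast"; below 4 valid laps the split is an error.
- The ANOVA returns F = 0 (not NaN) when the hypothesis sum of squares is
  numerically zero, including the doubly-degenerate all-identical case.
- Greenhouse–Geisser correction is conservative in the significance region;
  for F near 1 the corrected p can be marginally smaller — the property
  tests assert conservativity where p ≤ 0.2.
- Zero-variance inputs (baseline SD, correlation inputs, t-test samples)
  are signaled or marked undefined, never imputed.
- Sessions with fewer than two qualifying post-threat laps are discarded as
  `NA`, and cohort tables keep only mice usable in every session.

## Problem sizes

The test suite and the acceptance script use sizes chosen to estimate each
quantity stably: behavioral cohorts of 10–20 agents at 40–60 laps/session;
null calibration of the any-window rule with 5,000 outcome-independent
agents at 400 laps (per-window significance rate ≈ α; the family-wise
any-k rate is reported alongside, and is several times α, which is why the
per-window rate is the calibrated quantity); integration-window recovery
with 50 agents at 2,000 laps; neural probes of 100 cells × 240 laps,
averaged over three seeds.

## Known limitations

- The agent's speed model is linear in V with Gaussian noise; real approach
  speeds are skewed and bounded.
- `mixed_anova()` requires complete within-subject data (no imputation) and
  supports at most one between-subject factor.
- The history analysis follows the Pearson-with-any-k definition, including
  its lack of multiplicity control; a model-based lag regression would be a
  natural extension but is out of scope.
- The sign convention of the history correlation is reported as computed
  (per path, signed); interpretation is left to the user because adaptive
  behavior can produce either sign depending on the path coded.
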