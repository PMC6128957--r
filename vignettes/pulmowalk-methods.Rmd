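---
title: "Adaptive walking regimens and trial analytics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive walking regimens and trial analytics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmowalk)
```

## The problem

Home-based pulmonary rehabilitation for COPD patients replaces supervised
hospital sessions with app-guided daily walks, wearable pulse oximetry and a
central monitoring site. pulmowalk implements the computational core of such
a platform: the two adaptive walking regimens, the 6-minute walk test (6MWT)
analytics that seed them, in-session SpO2 alerting, the monitoring site's
compliance and flagging analytics, and the statistics of a three-arm
randomized trial evaluating the platform. A seeded simulator generates
synthetic COPD patients so the full pipeline can be exercised and tested
without any patient data.

## The two regimens

**Fixed regimen.** Six daily distance targets: 600, 1200, 1800, 2400, 3000,
3600 m. All walks sharing one calendar date are summed; a day whose total
reaches the target counts as one qualifying day (at most one per date), and
14 qualifying days — not necessarily consecutive — advance the level by one,
capped at the top. We read "achieving the distance within a day" as daily
accumulation rather than one continuous walk, because patients with severe
dyspnea walk in bouts; the daily credit and the non-consecutive count are
therefore deliberate design choices, both configurable through
`fixed_level_table()`.

**Interactive regimen.** Intensity is a prescribed walking *speed*:
`0.8 × v_max` from the most recent 6MWT, scaled by a per-level multiplier.
Level movement is driven by the post-session modified Borg score (0–10
breathlessness): three consecutive sessions at Borg ≤ 3 move the level up by
one; Borg ≥ 7 sustained over the same streak moves it down (floored at 1);
any score strictly between the thresholds clears both streaks. Reaching
level 12 schedules a repeat 6MWT, after which the base speed is re-derived
and the level resets to 7. The duration of "persists ≥ 7" is not fixed by
the platform description; we chose symmetry with the up-rule (3 consecutive
sessions) and exposed it as `streak_length`. The per-level speed multipliers
are likewise unspecified; the default table rises linearly from 1.00 to 1.22
(2% per level) over fixed 30-minute sessions, so that the top level demands
roughly the 6MWT maximum speed (0.8 × 1.22 ≈ 0.98 v_max) — a plausible
progression for a program anchored at 80% of v_max. Both are plain
arguments of `interactive_level_table()`.

**Metronome and alerting.** The app paces walks with a metronome; cadence is
`speed / stride_length × 60` steps/min with a configurable default stride of
0.70 m, typical of older COPD patients. The SpO2 monitor alerts at the first
sample strictly below 90%, suppresses repeats for a 30 s debounce while the
signal stays low, and re-arms immediately on recovery; threshold and
debounce are arguments. Only the 90% threshold is fixed by the platform;
debounce and re-arm are our alerting contract, chosen so a single
desaturation episode vibrates once rather than at every sample.

## 6MWT computation and eligibility

`compute_6mwt()` reduces an instantaneous speed trace on [0, 360] s to six
one-minute split speeds by time-weighted averaging under linear
interpolation (robust to uneven sampling), the walked distance as the exact
integral of the piecewise-linear trace, and the maximum walking speed as the
largest split. Trial eligibility uses strict inequalities as specified for
the study population: age > 20 years, FEV1 < 80% predicted, 6MWT > 150 m.

## The synthetic cohort

Each simulated patient carries a latent sustainable walking speed
(`capacity`), set to the baseline 6MWT distance over 360 s, with the
baseline distance drawn from N(356, 98) m truncated above 150 m and the
other demographics matched to a moderate COPD outpatient population
(age ~ N(64, 8), FEV1 ~ N(58.6, 15.8) truncated below 80, CAT ~ N(15.6, 7.8)).
The Borg response is linear in relative intensity
(`borg = round(borg_gain × prescribed/capacity + ε)`, clamped to [0, 10], ε
Gaussian with SD 0.5): the simplest monotone model that exercises every
branch of the feedback rules. SpO2 sits at
`baseline − desat_propensity × relative intensity` plus noise, clamped to
[70, 100]. Defaults — `borg_gain` 4.5, `desat_propensity` 5, baseline SpO2
96%, adherence 0.8/day, capacity growth 0.1% per completed session, dropout
hazard 0.0185/week (≈ 20% over 12 weeks, the design's dropout assumption) —
were chosen once as clinically plausible values; with `borg_gain` 4.5 a
patient starting at 80% of v_max reports Borg ≈ 4, inside the stable band,
so the noise-free feedback loop settles rather than oscillates, and lower
gains (fitter patients) climb several levels first.

Visit outcomes (V1/V2/V3 at weeks 0/6/12) are baseline scores plus
configured additive arm effects plus Gaussian noise, independent of the
walking trajectory; this keeps the null distribution of the outcome analysis
exactly exchangeable across arms, which the calibration tests rely on. What
the simulator does *not* model: heart-rate dynamics beyond noise around a
rising mean, weather/season effects on adherence, learning effects in the
6MWT, or any coupling between desaturation and capacity. Passing tests
therefore validate the platform logic and the analysis pipeline, not
clinical effect sizes.

## Trial statistics

`sample_size()` uses the two-sample normal-approximation formula
`n0 = 2((z_{1−α/2} + z_{power}) σ/δ)²` with δ = 50 m, σ = 60 m, α = .05,
power 80%, then inflates by 1/(1 − dropout) with 20% dropout and rounds to
the nearest integer — reproducing 28 per group, 84 total. Rounding to
nearest (rather than the conservative ceiling, 29) is the order of
operations that reproduces the published design; `rounding = "ceiling"` is
available. `empirical_power()` checks the design by simulation with a
vectorized pooled-variance t-test; at the unadjusted analytic n of 23 the
closed-form power is 78.9%, and Monte-Carlo estimates at 10,000 replicates
land within half a point of it.

`randomize()` stratifies by site, FEV1 %predicted and CAT. The published
design states 1:1:1 allocation stratified by FEV1 and CAT but not the
cut-points or block scheme; we chose the GOLD severity boundary
(FEV1 < 50%) and the standard CAT high-impact boundary (CAT ≥ 10), with
permuted blocks of size 3, all configurable.

`baseline_anova()` is the standard one-way between-groups ANOVA (via
`stats::aov`). `rm_anova()` fits the mixed between-within ANOVA
`y ~ arm × visit + Error(patient)` on complete cases with no sphericity
correction — the smallest faithful reading of a repeated-measures ANOVA of
visit changes — and reports per-arm change scores (V2−V1, V3−V1) alongside
the F tests, since a published within-group V2 comparison could be read
either way. Both return tidy()/glance()-able objects.

## Numerical and degenerate-input choices

Borg scores live on the half-point grid {0, 0.5, …, 10}; thresholds compare
with ≤ and ≥ exactly. Day boundaries are the local calendar date on the
record; no timezone arithmetic. `update_fixed()` requires strictly
increasing dates so a date can never be credited twice. Empty distance
tables, non-increasing levels, nonpositive 6MWT speeds, unsorted telemetry
and out-of-range scores are rejected with messages; session-log readers drop
invalid records with line numbers and fail only when nothing is valid.
6MWT integration is exact for piecewise-linear traces (trapezoid over the
knot grid augmented with minute boundaries), so the only approximation error
is the linear interpolation itself.

## Problem sizes used in the checks

The test suite replays 10,000 random Borg sequences (length ≤ 8) against a
brute-force oracle, calibrates the RM-ANOVA interaction p-value on 1,000
null simulations (3 × 8 patients each), recovers the Borg gain from 1,000
simulated sessions, and checks the 6MWT calibration on 1,000 drawn
patients; Monte-Carlo power uses 10,000 simulated trials. These sizes give
Monte-Carlo error comfortably below the tolerances asserted while keeping
the default run quick.

## Known limitations

The regimen engine is a faithful but minimal reading of the platform's
printed rules; details the platform leaves unstated (interactive level
content, high-Borg persistence, compliance day- vs session-counting) are
explicit, documented defaults rather than facts. The simulator is a testing
instrument: its effect sizes are configuration, not predictions, and the
package deliberately does not attempt to reproduce the original trial's
patient-level p-values, which depend on unpublished data.
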