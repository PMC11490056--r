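---
title: "Methods: fragmentation metrics, non-wear simulation, and reliability"
author: "actifrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentation metrics, non-wear simulation, and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the data
model, the eight rest-activity rhythm (RAR) fragmentation metrics, the
artificial non-wear machinery, the two missing-data treatments, the
reliability analysis, and the numerical and design choices made where
the methodology left room. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Data model

The unit of data is a per-subject sequence of 60-second epochs
(`EpochSeries`): an ENMO-like acceleration magnitude in milligravity
(mg), a wear flag, and a sleep/wake label per epoch, on a gap-free
grid — non-wear is a flag, never a missing row. Days are
*wake-to-wake*: a `DayPartition` holds wake onsets and sleep onsets,
with the day period `[wakeOnset, sleepOnset)`, the night period
`[sleepOnset, nextWakeOnset)`, and the entire day their union. All
intervals are half-open and a timestamp indexes the start of its
epoch, which makes bout and block arithmetic unambiguous.

When a partition must be recovered from the labels alone
(`derivePartition`, used by `readEpochCSV`), a wake onset is the start
of a *sustained* wake run (default ≥ 120 epochs = 2 h). Brief
nocturnal wake bouts therefore never open a new day; the matching
sleep onset is the first sleep epoch after the sustained run. Without
a minimum-duration rule, every wakeful interruption of fragmented
sleep would count as a day boundary.

Hourly aggregation is *wake-anchored*: hour 0 of each entire day
begins at that day's wake onset, giving 24 aligned slots per day. The
alternative, civil-clock binning, mixes behavioural phases whenever
wake times vary across days; since the day structure here is defined
wake-to-wake, anchoring at wake keeps slot h comparable across days.
Epochs beyond hour 23 of an entire day longer than 24 h (at most
about an hour under realistic wake-time jitter) are not assigned to
any slot.

## The eight metrics

**Interdaily stability.** On the pooled hourly series with N observed
values, 24 slot means $\bar x_h$ and grand mean $\bar x$:
$$IS = \frac{N\sum_{h=1}^{24}(\bar x_h-\bar x)^2}{24\sum_i (x_i-\bar x)^2}.$$
IS is 1 when every day repeats one profile and 0 when each day is
flat at its own level. For i.i.d. noise the ratio-of-expectations
value is $(N/D - 1)/(N-1)$ (D days), approximated by $24/N$; the test
suite verifies this by Monte Carlo (1000 replicates of 7 × 24 noise).
IS requires every slot observed on at least two days; otherwise it is
returned missing with the reason `insufficient hourly coverage`. The
denominator uses observed values only and N counts observed hours,
consistent with omission semantics.

**Intradaily variability.** The normalized mean squared successive
difference over adjacent observed hour pairs. With complete data it
is the textbook form $N\sum(x_i-x_{i-1})^2 / ((N-1)\sum(x_i-\bar
x)^2)$; with gaps it generalizes to (mean squared difference over
valid pairs) / (sum of squares / N), which reduces to the former when
no hour is missing. Pairs spanning an omitted hour are *skipped, not
bridged*: bridging would manufacture large spurious differences
exactly where data are missing. Closed-form anchors: a ramp over N
hours gives $12/(N^2-1)$; an alternating series gives 4.

**Transition probabilities.** Epochs are binarized — day period:
rest if acceleration is *strictly below* 40 mg (40.0 itself is
active), active otherwise; night period: the sleep/wake label,
regardless of acceleration. Maximal same-state runs are extracted
within each (day, period) instance; a run touching a period boundary
or a non-wear gap is flagged censored on that side. Each per-epoch
transition probability is the reciprocal of the mean duration of
*uncensored* bouts of the originating state, pooled over all retained
days. Censored bouts are excluded because truncated durations bias
the mean downward. The estimator is exact for first-order two-state
dynamics (geometric bouts) and the suite recovers (0.2, 0.4) within
±0.01 from a 10^5-epoch chain.

One estimator property worth knowing: excluding boundary-touching
bouts slightly over-excludes *long* bouts (a length-biased selection),
so TP estimates carry an upward bias of order (mean bout length) /
(period length). For day bouts of a few minutes in a 16-h day period
this is negligible; for 20-min sleep bouts in an 8-h night it is a
few percent. The recovery test bounds the error by three Monte-Carlo
standard errors plus a 1/period-length allowance.

**DFA alpha.** First-order detrended fluctuation analysis: center,
integrate, split into non-overlapping boxes of size s, remove a
linear trend per box, F(s) = RMS residual, alpha = unweighted OLS
slope of log F(s) on log s. The box grid is 12 log2-spaced integers
in [10, min(N/4, 90)] epochs. The lower bound follows standard DFA
guidance (boxes under ~10 points bias F(s) upward for correlated
series; calibration on white noise / fGn(H = 0.9) / random walk at
n = 2^14 sits at ≈ 0.50 / 0.90 / 1.48 on this grid, verified in the
suite). The upper bound of 90 epochs (90 min) keeps the fit below the
ultradian/circadian crossover so alpha measures bout-scale fractal
dynamics, and — decisive for a reliability study — makes the fitted
scale range *identical across recordings of different lengths*. With
a length-dependent bound such as N/4, the daily cycle enters the
largest boxes only for longer recordings, so mean alpha drifts with
the number of retained days; absolute-agreement ICC reads that drift
as disagreement even when subjects keep their rank order. Under
omission, the observed epochs are concatenated (gaps closed) rather
than interpolated; series shorter than 256 epochs or with zero
variance return a missing alpha with a reason.

**ABI.** $ABI = \exp(-|\alpha-1|/e^{-2})$, a bounded transform
peaking at alpha = 1 and symmetric in $|\alpha - 1|$; the scale
constant is an argument for users who prefer a different decay.

## Synthetic cohorts

`generateCohort` produces the statistical structure the reliability
analysis assumes, with known ground truth where one exists:

- Daily wake and sleep-onset times drawn per day (defaults 07:00 and
  23:00, sd 0.5 h each), rounded to the 60-s grid, giving ~16-h day
  and ~8-h night periods.
- Two-state first-order Markov bout dynamics per period. Day:
  rest→active 0.30, active→rest 0.25 per epoch (mean bouts ~3 and
  4 min — a fragmented waking day). Night: wake→sleep 0.35,
  sleep→wake 0.05 (mean sleep bouts ~20 min, wake bouts ~3 min,
  sleep efficiency ~87% — the fragmented sleep typical of older-adult
  wrist actigraphy; a consolidated-sleep regime would leave so few
  uncensored sleep bouts per night that the bout-based TP estimator
  becomes heavy-tailed and its reliability uninformative).
  Night chains are conditioned (by rejection) to begin and end
  asleep, since the night period by construction runs from sleep
  onset to the epoch before wake onset; this also makes the labels
  recover the partition exactly on re-read.
- State-conditional lognormal acceleration (rest ~15 mg, active
  ~120 mg), truncated so rest stays strictly below 40 mg and activity
  at or above it — binarization recovers the latent state exactly,
  isolating metric correctness from threshold noise.
- A lognormal per-day level multiplier (`dayToDayJitter`, default sd
  0.15) creating day-to-day variability (so IS < 1 and agreement
  genuinely improves with more days), and subject-level heterogeneity:
  logit-normal subject effects on all four transition probabilities
  (`tpSubjectSd`, default 0.4) and lognormal subject multipliers on
  the level means (`levelSubjectSd`, default 0.25). Between-subject
  variance is what ICC measures; a homogeneous cohort would make
  reliability undefined. Tests that need exact parameter recovery set
  these to zero.

Only the transition probabilities have a closed-form ground truth
under this generator; IS, IV and alpha are validated against
constructed signals and reference noise instead (white noise, exact
circulant-embedding fractional Gaussian noise, random walks). The
generator emulates circadian day/night organization, bout dynamics,
level heterogeneity and seeded reproducibility; it does not emulate
device noise, posture artifacts, naps, weekday/weekend structure, or
behaviourally clustered non-wear, so passing tests speak to the
correctness and statistical behaviour of the pipeline, not to any
particular human population.

## Non-wear scenarios and valid days

Scenario 1 (valid day = wear ≥ 2/3 of the entire day) inserts one
block per entire day: length uniform on the integers
[1, ⌊W/3⌋] epochs (W = the day's wear epochs), start uniform over
positions keeping the block inside the day. Scenario 2 (valid day =
wear ≥ 2/3 of both day and night periods) inserts one such block per
period, independently, each capped by a third of that period's wear.
Scenario 3 (valid day = complete wear) inserts nothing. Because
lengths are capped at a third of wear, every masked day still
satisfies its own scenario's criterion — an invariant the suite
checks, along with uniformity of the block-length distribution and
the ~1/6 expected non-wear fraction that `scripts/acceptance.R`
recomputes by Monte Carlo.

Batches cross scenarios 1–3 with 1–7 retained days, minus
(scenario 3, 7 days), which is the reference: 20 batches. Batches
retain the *first* n entire days — a deterministic choice mimicking a
shortened wear protocol. Masks only ever switch wear off;
accelerations are untouched.

Mask randomness is organized as one stream per (scenario, subject),
with per-day draws taken sequentially, so the n-day batch carries the
first n masked days of the scenario's full mask set. These *nested*
masks are a common-random-numbers design: comparisons across numbers
of retained days then reflect the data removed, not independent
redraws of where the blocks happened to land. Within a scenario,
adding batches never perturbs existing ones; across scenarios and
subjects, streams are independent.

## Omission and imputation

*Omission* excludes non-wear epochs from every computation while
preserving clock positions (hourly slots keep their place; bouts
abutting a gap are censored; the DFA series concatenates what
remains). *Imputation* fills each non-wear epoch with the mean
acceleration at the same wake-anchored offset within the entire day
across the other retained days where the device was worn — "the same
moment of the day" is behavioural phase, not civil clock time, since
days are wake-to-wake. Night epochs also need a state for the TPs:
the sleep/wake label is imputed by majority vote across the donor
days, ties resolved to sleep (the night-period prior). Positions
unobserved on every donor day are left missing with a warning (those
epochs fall back to omission). Observed epochs are never altered, and
filled epochs carry an `imputed` provenance flag written to the CSV
dialect. Because the cross-day mean has lower variance than any
single day, imputed stretches are smoother than what they replace —
the suite verifies this, and it is the mechanism by which imputation
inflates similarity-type metrics such as IS.

## Reliability

Each batch × handling × metric cell pairs per-subject batch values
with the reference values (scenario 3, complete 7 days),
complete-case within metric. Agreement is ICC(A,1): two-way,
absolute-agreement, single-measures intraclass correlation with k = 2
raters,
$$ICC(A,1) = \frac{MS_R - MS_E}{MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E)},$$
computed from the mean squares directly and cross-checked in the
suite against a `stats::aov` decomposition to 10^-10. Absolute
agreement (rather than consistency) is the conservative choice for a
method-agreement design because it penalizes systematic bias. Error
is MAPE = 100 · mean |sim − ref| / |ref| with a 10^-8
reference-magnitude floor (near-zero references are excluded and
counted rather than allowed to blow up the mean). Cut points default
to ICC ≥ 0.75 and MAPE ≤ 15%.

IS rows are excluded below three retained days: IS needs every hour
slot observed at least twice, so shorter batches can only compute IS
for the accidental subset of subjects whose blocks overlapped in
clock time — a selected subsample that would not estimate the
cohort's reliability. The minimum-days decision uses a terminal-run
rule: the smallest n such that n and every larger tested n pass both
cut points (a recommendation that fails again at more days is not
usable). Strata (sex, age group) rerun the whole table within each
level; strata under 3 subjects are skipped.

## Problem sizes and reproducibility

The validation suite uses: closed-form fixtures (seconds); 10^5-epoch
chains and 2^14-point noise series for parameter recovery (under a
minute); 50-instance brute-force oracle sweeps for IS/IV/ICC/MAPE;
and one heterogeneous 500-subject, 7-day cohort on which the
reliability structure is checked (ICC non-decreasing in retained days
within a 0.03 tolerance; complete wear agreeing at least as well as
the split-period scenario; IS under imputation not beating IS under
omission beyond 0.02) — a few minutes of compute chosen to keep the
Monte-Carlo noise of ICC at n = 500 near the tolerances being
asserted. All randomness flows from explicit seeds through named
substreams (cohort, per-scenario masks, per-subject), and identical
configuration plus seed reproduces byte-identical decision output;
the suite asserts this.

## Known limitations

- The generator's bout dynamics are first-order Markov; real
  rest-activity data show heavier-tailed bout distributions, so
  absolute reliability levels on real cohorts may differ from the
  synthetic ones (the qualitative ordering is what the tests assert).
- Epoch length is fixed at 60 s and the metric set at the eight
  above; cosinor, M10/L5 and sleep-fragmentation indices are out of
  scope.
- Raw-signal processing (calibration, sleep detection, device
  non-wear detection) is upstream: inputs must already carry wear
  flags and sleep/wake labels.
- The TP estimator's boundary-exclusion bias (above) is intrinsic to
  censoring-aware bout pooling; hazard-based estimators would trade
  it for model assumptions.
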