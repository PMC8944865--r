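---
title: "Methods: from wrist acceleration to a landscape of sleep phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist acceleration to a landscape of sleep phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepscape)
```

# Overview

`sleepscape` implements a complete actigraphy phenotyping pipeline:

1. triaxial acceleration → epoch-level sleep/wake series
   (jerk-spectrum features, gradient-boosted classifier, nonwear
   detection);
2. sleep/wake series → sleep windows → 21 per-subject sleep indexes
   (quantity-related daily features plus rhythm-related circadian
   features);
3. index table → z-scoring → low-dimensional embedding → density
   clustering, applied divisively, with Ward regrouping and a percentile
   outlier branch.

Every stage is testable without device data through a synthetic-cohort
simulator that plants known sleep structure and emits matching
acceleration traces. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic evidence does
and does not establish.

# Sleep/wake scoring

**Features.** Movement, not posture, distinguishes wake from sleep on the
wrist, so the classifier works on jerk — the first difference of
acceleration times the sampling rate — which cancels gravity and any
constant offset (feature extraction is therefore translation-invariant by
construction). Each 30-s epoch of jerk is converted, per axis, to a
rectangular-window periodogram integrated over 8 log-spaced frequency
bands from 0.1 Hz to Nyquist, plus the epoch variance as a total-power
feature (27 features at three axes). The band sum reproduces the epoch
variance up to the spectrum below 0.1 Hz (Parseval), which the tests
check on white noise.

**Classifier.** An XGBoost binary model (depth 4, 200 trees, learning
rate 0.1, single thread for determinism) with sleep as the positive
class; the reported training objective is accuracy + F measure on a
held-out epoch fraction. Hyperparameters are fixed defaults rather than
searched: on the synthetic cohorts the problem is benign, and the choice
keeps runs reproducible. On held-out synthetic subjects the classifier
reaches epoch sensitivity ≥ 95% and specificity ≥ 80% — the performance
regime the design targets. Because synthetic sleep/wake noise is
Gaussian with state-dependent SD plus wake movement bursts, this result
demonstrates pipeline correctness, *not* device-grade accuracy: real
accelerometry has posture artifacts, restless sleep, and device-specific
noise that the simulator does not emulate.

**Nonwear.** A 60-min window stepped by 15 min is flagged when at least
two axes have SD < 13 mg *or* range < 50 mg (strict comparisons); flags
propagate to all covered epochs and union over windows. The thresholds
follow the established accelerometry nonwear rule; they sit between
off-wrist noise (≈ 1 mg) and the simulator's sleeping-wrist noise
(15 mg), and raising either threshold can only add flags (monotonicity is
tested). Masked epochs become missing (`M`) and are excluded pairwise
from every evaluation.

# Sleep windows and daily indexes

Scoring noise produces spurious short bouts, so the series is smoothed by
two fixed passes: wake runs shorter than 10 min flanked by sleep are
flipped to sleep, then sleep runs shorter than 10 min flanked by wake are
flipped to wake. The pass order is fixed and documented because the two
orders differ on adjacent short runs; missing epochs break runs and are
never flipped. The 10-min default is justified empirically by
`evaluate_smoothing_threshold()`, which sweeps thresholds on pseudo
series corrupted with short planted flips.

Sleep windows connect sleep runs separated by wake gaps of at most
60 min (inclusive); a missing epoch inside a gap conservatively breaks
the merge, which keeps the identity `st + wt = window length` exact.
Windows longer than 3.75 h are *long*, others *short* (a window of
exactly 3.75 h is short). Days run noon-to-noon so nights are never
split; a window belongs to the day containing its onset and is not split
at noon. Midawake bouts are wake runs between the day's first window
onset and last window offset, long-term when ≥ 60 min and short-term
below — because merges are inclusive at 60 min, gaps *between* windows
are exactly the long-term midawakes, which reconciles the two
conventions. Sleep percentage counts every sleep epoch of the day,
inside or outside windows, so it dominates `(st_long + st_short)/24`
with equality when no sleep falls outside windows.

A record is analysable when it contains a run of at least 4 consecutive
noon-to-noon days with strictly less than 5 h of nonwear each, capped at
7 days ("more than 3 days" is read strictly; both the minimum and the
strictness are configurable). The 21-index vector comprises 3 general
features (period, amplitude, total window count) and mean/SD over valid
days of 9 daily features (phase, ST/WT long/short, sleep percentage,
long/short window length, long-window count). SD uses the n−1
denominator and is defined as 0 for a single day.

# Rhythm indexes

**Period** comes from the chi-square periodogram of wake minutes per
10-min bin: for each candidate period that is an integer number of bins
between 5 and 35 h, the series is folded into K columns and
`Qp = N·K·Σ_h(M_h − M̄)² / Σ_i(x_i − M̄)²` is compared with the
chi-square `1 − α` quantile (α = 0.01, K − 1 df); the estimate maximises
`Qp − sig` with ties to the smallest period. The grid step is one bin
(10 min ≈ 0.167 h) because folding requires integer columns. A caveat
inherent to the statistic: folding aligns exactly at integer multiples of
the true period, and competitively at small-ratio rational multiples, so
a planted period recovers *exactly* only when even its 3/2 multiple falls
off the grid (true period > 23.3 h for a 35-h maximum); shorter planted
periods recover as exact multiples. The circadian range of interest sits
safely in the exact regime, and the tests assert both behaviours.

**Amplitude** is the population CV (SD/mean) of wake minutes per bin
over the whole record — scale-invariant, zero for constant wake, √2 for
a {0,10} duty-1/3 square wave and 4√2/13 for the {3,7} variant (both
asserted to 1e-9 as closed forms).

**Phase** is fitted per noon-to-noon day: epochs are encoded wake = 1,
sleep = 0, missing = 0.5, and the van der Pol limit cycle
(`ẍ − μ(1−x²)ẋ + ω²x = 0`, μ = 1 by default, numerically integrated to
its cycle, min-max normalised, minimum rotated to phase 0, rescaled to a
fixed 24-h period) is shifted circularly on a 1-min grid to minimise the
SSE; the fit is computed for all shifts at once by FFT cross-correlation
and verified against a brute-force loop in the tests. Phase is the
elapsed time from the preceding noon to the fitted minimum, in (0, 24]:
a minimum at midnight gives 12 h, later minima give larger phases (a
night-owl's minimum at 03:30 gives 15.5 h). The fixed 24-h waveform (not
the estimated period) is used because phase is defined against clock
noon and the per-day SD already captures drift; phase statistics are
naive (non-circular) means/SDs, adequate while per-subject phases
cluster well away from the 0/24 wrap. μ is not fitted per subject; the
μ → 0 limit approaches `(1 − cos)/2` (tested at μ = 0.01 within 2%).

# Clustering the landscape

Indexes are z-scored column-wise (n−1 SD; zero-variance columns become 0
with a warning; the transform is invertible). The default embedding is
UMAP to 3 dimensions (n_neighbors 50, min_dist 0, single-threaded SGD
for seed determinism); PCA, t-SNE and PCA→UMAP are selectable. DBSCAN
with `min_samples = 20` clusters the embedding; when `eps` is not given
it defaults to 5× the median distance to the 20th nearest neighbour.
This heuristic adapts to the embedding's scale (UMAP and PCA axes differ
by orders of magnitude) and deliberately errs large: an oversized eps
merges everything into one cluster, which the divisive wrapper treats as
"no split" — a safe stop — whereas an undersized eps shatters genuine
clusters irrecoverably.

The divisive wrapper re-z-scores each node's members, embeds, clusters,
and accepts a split only when at least two children reach 20 members;
smaller children fold into the largest accepted sibling so children
always partition their parent, and DBSCAN noise at a node is recorded
and excluded from its subtree. Recursion stops at depth 3. Leaves are
then regrouped by Ward's method (`ward.D2` on the leaf mean z-profiles)
independently within each first-layer cluster — never across — and
relabelled `2a`, `2b`, …; regrouping on cluster-mean profiles rather
than all points matches the granularity at which the divisive leaves are
interpreted.

The outlier branch flags subjects falling at or below the 2.28th or at
or above the 97.72nd percentile (linear-interpolation quantiles,
inclusive boundaries; 2.28% is the two-SD tail of a normal) of any of
six configurable indexes — by default WT long MN, ST long SD, ST short
MN, sleep percentage MN, phase MN, and period — and re-clusters the
flagged subset from scratch. For independent continuous indexes the
flagged fraction converges to `1 − (1 − 0.0456)^6 ≈ 0.244`, which the
tests check within 3 standard errors at n = 20,000.

# The synthetic cohort

The simulator is structural rather than dynamical: each night's onset
and duration are drawn explicitly (clock-time onset with Gaussian
jitter, drift of `circadian_period − 24` h/day, optional weekend shift),
midawake bouts arrive Poisson per night with a configurable probability
of being long-term (≥ 60 min), and naps land in the early afternoon.
This makes every planted parameter directly recorded as ground truth;
the van der Pol model is reserved for fitting, so generator and fitter
share no machinery. Acceleration traces add state-dependent Gaussian
noise (sleep 15 mg, wake 60 mg per axis) plus Poisson-arriving 1–10 s
oscillatory wake bursts, and near-constant signal (1 mg) inside declared
nonwear spans; the sleeping-wrist SD is set above the 13 mg nonwear
threshold so sleep is never mistaken for nonwear. Per-subject seeds
derive from the master seed, the archetype name, and the within-archetype
index, so cohorts are reproducible, extensible, and invariant to the
order of archetype specifications.

Four built-in archetypes (regular; fragmented insomnia-like short sleep;
phase-delayed night person; 25-h period) provide the cohort used in the
clustering recovery check. What passing that check shows is that the
pipeline separates phenotypes whose index profiles genuinely differ; it
does not show that real populations form such well-separated groups —
real index distributions are continuous, and cluster boundaries there
depend on the embedding and density parameters in ways the synthetic
cohort cannot probe.

# Problem sizes and numerical choices

The test-suite and acceptance computations use deliberately moderate
sizes chosen as the smallest that make each property statistically
unambiguous: 1,000 random series for the exact window/smoothing oracle
comparisons, 200 simulated days for phase recovery (10% epoch noise,
0.5 h tolerance), a 70-subject single-day cohort at 10 Hz for the
classifier regime (50 train / 20 test), 2,000 subjects × 6 days for
clustering recovery, and 20,000 subjects for the outlier fraction.
Degenerate inputs are first-class: constant binned activity is a
periodogram error (zero variance), zero-mean bins an amplitude error,
days with < 50% coverage a phase error, series without sleep yield empty
window lists, and cohorts with no valid span stop the pipeline with an
explicit report status. Ties break deterministically everywhere: the
smallest period on the Qp grid, the smallest shift in phase fitting, the
earliest run in span selection, the lowest id among equidistant cluster
representatives.

# Known limitations

- Binary sleep/wake only; no sleep staging, no apnea-related signals.
- The classifier is trained and validated on synthetic traces; applying
  it to device data requires retraining on labelled recordings.
- Naive (non-circular) phase statistics bias the phase SD for subjects
  whose minima straddle noon — rare for human sleep but possible for
  extreme phenotypes.
- The periodogram grid is limited to integer bin multiples; periods are
  reported at 10-min granularity.
- UMAP + DBSCAN results depend on seeds and density parameters; the
  divisive stop rule and Ward regrouping bound, but do not remove, that
  sensitivity.
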