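---
title: "Monitoring postoperative hemodynamic trajectories with multivariate control charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring postoperative hemodynamic trajectories with multivariate control charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemospm)
```

## The monitoring problem

A patient recovering from cardiac surgery is a *dynamic* process: the
vital signs of a normally recovering patient follow a shared trajectory
(an arterial-pressure dip and recovery over the first day, a slow decline
in SpO₂ as support is weaned) with patient-to-patient variation around
it.  Fixed univariate alarm thresholds ignore both the trajectory and the
strong correlations between signals.  `hemospm` adapts the machinery of
batch-process statistical process monitoring: treat each patient as a
batch, learn the cohort's trajectory and covariance from previously
successful patients, and chart each new patient's statistical distance
from that reference in real time.

The five monitored signals are heart rate (bpm), invasive systolic,
diastolic and mean arterial pressures (mmHg), and pulse-oximetry SpO₂
(%), on a common 1-minute grid of minutes since operation end
(default horizon 7 days = 10,080 minutes).

## Preprocessing

Raw streams arrive irregularly sampled.  Per signal:

* **Dropout detection** — any run of at least `dropout.min_gap = 3`
  consecutive grid minutes containing no raw sample is a dropout
  (the threshold is inclusive: 3 silent minutes already count).
* **Resampling** — values at integer minutes by linear interpolation
  between neighboring raw samples.  Interpolation never bridges a
  dropout; sub-threshold silences (1–2 minutes) are interpolated across.
  Minutes before the first or after the last sample are marked invalid
  rather than extrapolated.  Ordering matters: dropouts are found first,
  so a gap can never be "healed" by interpolation.
* **Hampel outlier cleaning** — for each valid point, the median and MAD
  over a centered `hampel.window = 11`-minute window (truncated at edges,
  restricted to valid entries) are computed; the point is flagged when
  its distance from the window median exceeds `t · 1.4826 · MAD` and
  replaced by that window median (single pass, no re-iteration).

### The Hampel threshold and its misidentification rate

The identifier's defining parameter is the *allowed misidentification
rate* `hampel.alpha = 0.05`: the probability of flagging an
uncontaminated Gaussian point.  The textbook multiplier
`t = z₁₋α/₂ ≈ 1.96` attains that rate only asymptotically in the window
width.  At window 11 the window median and MAD are noisy enough that the
asymptotic multiplier flags ≈ 9 % of clean iid Gaussian data — nearly
twice the nominal rate.  The package therefore calibrates the multiplier
by its definition: `t` is the 1−α quantile of the null ratio
`|x − median| / (1.4826 · MAD)` over windows of the configured width,
estimated once by Monte Carlo (2 × 10⁵ windows, fixed internal seed,
cached per window/α).  For window 11 and α = 0.05 this gives `t ≈ 2.48`
and a measured flag rate of 0.050 on iid Gaussian input.  The asymptotic
multiplier remains available (`hampel.threshold = "asymptotic"`).

Two deliberate conventions: a window with MAD = 0 (locally constant
readings, plausible at 1-minute resolution) never flags, since any
deviation would otherwise be flagged; and the filter is a single-pass
identifier — its output is *not* a fixed point, because replacing a spike
with the window median shrinks neighboring MADs, so re-running it can
flag further points.  Calibration holds for serially independent data;
on smooth (strongly autocorrelated) physiologic series the realized flag
rate is lower (≈ 2–3 % under the default generator), which is also the
regime in which a few-percent outlier rate on real recordings should be
read.

A record is flagged **excluded** when any sensor is invalid for more than
10 % of the monitoring horizon; exclusion flags but never silently drops
a patient — the pipeline refuses excluded records unless
`exclusion.override` is set.  Pre/post-admission gaps (before the first
or after the last measurement) are tallied separately from dropouts,
which are reported as fractions of each signal's recorded span.

## Batch-wise normalization

The cohort is stacked into an I × J × K array (patients × signals ×
minutes).  Each signal is augmented with `lags.n = 2` time-lagged copies
(J = 15), placed adjacent to their base signal; minutes k < lag are
invalid rather than padded, since padding would fabricate pre-operative
data.  Lagged columns are normalized with their own per-(column, minute)
statistics, which is identical to lagging the normalized base signal.

Batch-wise unfolding standardizes every (column, minute) cell across
patients — mean 0, SD 1 over the valid patients — which removes the
shared recovery trajectory *and* its time-varying variability.  SpO₂ is
the exception: all its columns are anchored at a fixed 100 % mean and 5 %
SD, reflecting that saturation has an absolute clinical reference rather
than a cohort-relative one (a patient at 95 % maps to −1 regardless of
the cohort).  Numerical safeguards: cells with fewer than 2 valid
patients inherit the statistics of the nearest valid minute of the same
column; SDs are floored at `10⁻³ ×` the column's median SD (with an
absolute floor of `10⁻⁸`) so that division stays bounded in
small cohorts.

The normalized tensor is then unfolded **variable-wise** into an
(I·K) × J matrix whose rows are the (patient, minute) pairs with all J
entries valid, in patient-major, time-minor order; the row index is kept
so scores can be folded back into per-patient minute series.  A monitored
patient's minutes with any invalid lagged entry become chart *gaps*,
never alarms.

## Latent-variable models

**PCA.** With `B = XᵀX/(n−1) = UΛ²Uᵀ`, scores are `S = XUΛ⁻¹`.  The
`1/(n−1)` scaling is chosen so the training-score covariance is exactly
the identity — the property the χ² chart limits rest on.  Columns are
re-centered before the decomposition (the fixed SpO₂ anchor can leave a
nonzero mean) and the training mean is stored.  Loadings signs are fixed
(largest-magnitude entry positive) for reproducibility across LAPACK
backends; singular values below `10⁻⁸ ×` the largest are treated as rank
deficiencies and their scores pinned to 0.

The retained count defaults to `pca.c = 3`.  Automatic selection
(`pca.c = NULL`) finds the knee of the scree curve — the index of maximum
discrete curvature of log eigenvalue versus index, ties to the smaller
count — and falls back to the smallest count reaching
`pca.coverage = 0.98` cumulative variance when the spectrum is flat.

**SFA.** The data are sphered with the PCA factors, `Z = XUΛ⁻¹`, and the
covariance `A = ŻᵀŻ/(n_deriv − 1)` of the backward differences of `Z` is
eigen-decomposed, `A = PΩPᵀ`.  Slow-feature scores `S = XUΛ⁻¹P` are
ordered by ascending Ω (mean squared derivative of a unit-variance
feature).  Differences are taken only *within* a patient's contiguous
valid spans — differencing across patient boundaries or gaps would
fabricate huge derivatives.  The slow-feature count defaults to
`sfa.d = c`.  Because P is orthonormal, PCA and SFA scores carry the same
total energy per observation; they differ only in how that energy is
partitioned, by variance (PCA) versus by time scale (SFA).

## Control charts

All charts use `charts.alpha = 0.01`.  With identity training-score
covariance:

* **T²** (retained PCA block): `‖s₁:c‖²` against the flat limit
  χ²₍c₎(0.99) ≈ 11.34 for c = 3.
* **SPE** (residual PCA block): `‖s₍c+1₎:J‖²` against the Box
  moment-matching limit `g_k χ²ₕₖ(0.99)` with `g_k = v_k/(2m_k)`,
  `h_k = 2m_k²/v_k`, where `m_k, v_k` are the mean and variance of the
  training cohort's SPE near minute k.  The raw training SPE values are
  pooled over a centered `spe.window = 5`-minute window *before* the
  moments are computed — pooling samples is the stabler small-cohort
  reading of windowed-limit smoothing (smoothing the moments afterwards
  is nearly equivalent at these window sizes).  `h` is real-valued, so
  the non-integer-degree χ² quantile is used.  Minutes whose pooled
  variance vanishes inherit the nearest computable limit.
* **T²,d / T²,e** (slow/fast SFA blocks): `‖s₁:d‖²` and `‖s₍d+1₎:J‖²`
  against χ²₍d₎(0.99) and χ²₍J−d₎(0.99).  Slow features track
  operating-point drift; fast features, abrupt anomalies.

Alarms are raw limit crossings (`alarms.min_duration = 0`); a
sustained-alarm filter is available but off by default, since spark
charts conventionally show every crossing.  `alarm_sparks()` extracts
maximal alarmed runs as half-open minute intervals, with gaps breaking
runs.

### What the χ² limits do and do not promise

The χ² limits are exact only against the *true* normalization and
whitening.  Estimated from I training patients, the held-out z-scores
have variance inflated by roughly `(1 + 1/I)(I−1)/(I−3)` (≈ 8 % at
I = 40), so the realized false-alarm rate exceeds the nominal α — about
0.015–0.018 rather than 0.010 at I = 40 in the package's own calibration
runs.  Moreover, physiologic noise is slow: a patient's statistic series
is strongly autocorrelated, so empirical exceedance pooled over a
*finite* monitored group is dominated by a few patients whose whole
series sits high (observed spread ≈ 0.003–0.04 over 20 monitored
patients).  The nominal rate is approached as both the training and the
monitored cohort grow; at clinical cohort sizes the limits should be read
as approximate.  Corrected (e.g. F-distribution) limits are a deliberate
non-goal: the χ² construction is the one whose behavior is being studied.

## Leave-one-out evaluation

`loo_monitor()` refits *everything* — normalization, PCA, SFA, SPE
limits — on each fold's training patients and scores the held-out patient
against that fold's models, so no patient influences their own charts.
The per-time normalization is refit within every fold (the alternative, a
single global normalization, would leak the held-out patient's data into
their own reference).  A fixed `c = 3` is used for every fold by default,
with each fold's cumulative variance logged; per-fold re-selection via
the L-curve is a config switch.

## The synthetic cohort generator

Real recordings of this kind are not redistributable, so the generator is
a first-class module with declared ground truth.  Per base signal it
draws:

* a **baseline curve** (piecewise linear in time): near-static HR
  (152 → 140 bpm over the week), ABP channels dipping around hours 6–12
  and recovering through day 1 (e.g. mean ABP 55 → 44 → 62 mmHg), SpO₂
  declining slowly from 100 % to 97 %;
* a patient **offset**: one Gaussian draw per signal, correlated across
  signals, scaled by the between-patient SD (HR 10, sys 8, dia 5, mean 6,
  SpO₂ 1.2 units);
* **within-patient noise**: an AR(1) process with coefficient 0.95 at
  1-minute lag (generated on a 0.25-minute grid with the correspondingly
  rescaled coefficient) and stationary SD of 4, 5, 3, 4, 0.8 units, with
  innovations correlated across signals (ABP channels 0.6–0.85, HR
  weakly negative against ABP, SpO₂ weakly positive).

These numbers are the package's own illustrative choices of a plausible
postoperative cohort; every quantitative test compares against *these
declared values*, not against any clinical dataset.  Streams are emitted
as irregular raw samples (every ~0.5 minutes with ±0.1-minute timestamp
jitter) to exercise resampling, and `inject()` / `inject_missingness()`
add mean shifts, variance inflation, correlation breaks, spike trains,
dropout gaps and isolated outliers with exact bookkeeping.

What the generator does **not** emulate: non-Gaussian and clipped
marginals (simulated SpO₂ may slightly exceed 100 %), heavy-tailed
artifact bursts, regime switches (sedation, procedures), inter-patient
heterogeneity of dynamics (every patient shares one AR coefficient), and
multi-modal recovery subgroups.  Passing tests therefore demonstrate
correctness of the machinery under a known Gaussian trajectory model, not
clinical validity on real recordings.

## Numerical and design choices, in brief

* Integer minutes, 0-based, half-open intervals everywhere; coarse note
  time frames map to fixed 6-hour blocks (night [00–06), morning
  [06–12), afternoon [12–18), evening [18–24)) of the stated day.
* Interchange formats are plain CSV (long format, one row per
  (patient, signal, minute) or (patient, signal, time)); charts
  round-trip at 17 significant digits; model bundles serialize to
  JSON/CSV.
* Problem sizes in the shipped tests and the calibration script — up to
  60 patients at a 1440-minute horizon, 10⁵-point Hampel runs — were
  chosen as the smallest sizes at which the Monte-Carlo tolerances of the
  assertions are meaningful; all complete in seconds.
* Detection-power checks inject the diastolic-only episode (a
  correlation-breaking fault, the clinically typical presentation).  A
  *coherent* shift of all three ABP channels is intrinsically harder:
  it points along the dominant between-patient correlation direction, so
  its Mahalanobis distance — and hence T² power — is much smaller at the
  same per-signal magnitude.

## Known limitations

Single recovery phase and a single model per cohort (no clustering of
recovery subtypes); no fault reconstruction or per-variable contribution
charts; no adaptive or EWMA/CUSUM variants; χ² limits are approximate at
small I (above); the Hampel calibration targets serially independent
noise.  These mirror the boundaries of the monitoring framework itself
rather than missing engineering.
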