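---
title: "Detecting and calibrating burst suppression in frontal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and calibrating burst suppression in frontal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstsupp)
```

## The detection model

Burst suppression (BS) in the anesthetised EEG alternates high-amplitude
polyphasic bursts with low-amplitude suppressed periods. `burstsupp`
operationalises detection as a chain of elementary, individually testable
stages:

1. **Envelope.** For each channel, the amplitude envelope is the centred
   moving average of the rectified signal over `w_env` seconds
   (`amplitude_envelope()`). The window is truncated at the record edges
   rather than padded: no samples are fabricated and the estimate has no
   phase lag. With `w_env` equal to one sample the envelope degenerates to
   `|x|`, which is the brute-force oracle that the test suite compares the
   whole suppression stage against.
2. **Suppression thresholding.** Maximal runs with envelope below
   `theta_supp` that last at least `d_supp_min` seconds become suppression
   intervals (`detect_suppressions()`). All intervals are half-open
   `[onset, onset + duration)` on the sample grid, so abutting intervals
   never overlap and duration sums are unambiguous.
3. **All-channel consensus.** Suppression is only accepted where every
   channel is suppressed simultaneously: the per-channel suppression masks
   are AND-ed per sample, and the result is re-extracted and re-filtered by
   `d_supp_min` (`consensus_suppressions()`). Applying the consensus on
   masks (rather than on delimited epochs) is the stricter of the two
   readings and is deterministic; epochs are delimited afterwards on the
   consensus track.
4. **Bursts.** Candidate bursts are the gaps between consecutive
   suppressions; a candidate qualifies if it lasts ≥ `d_burst_min` and its
   waveform is polyphasic, i.e. contains at least `n_phases_min` phases
   (`detect_bursts()`). A phase is one half-wave, counted as interior
   baseline crossings of the mean-subtracted segment plus one. Taking the
   segment mean as the baseline makes the count invariant to DC offset; the
   corner case it implies is documented below.
5. **Epochs and summary.** Suppressions separated by at most `g_max`
   seconds are chained into one BS epoch spanning from the onset of its
   first to the end of its last suppression (`delimit_bs_epochs()`).
   `detect_bs()` reports the cumulative consensus-suppressed time
   (`bs_duration`), the epoch span, and the burst-suppression ratio
   `bsr = 100 * bs_duration / analysed time`. The binary indicator
   `any_bs` is always derived as `bs_duration > 0`, never stored
   independently.

### Parameters

| parameter      | unit | default | rationale |
|----------------|------|---------|-----------|
| `theta_supp`   | µV   | 5       | the amplitude criterion used by common BS-probability algorithms (e.g. the BIS suppresses below 5 µV for > 0.5 s); calibration re-estimates it from annotations |
| `w_env`        | s    | 0.5     | long enough to average over a full cycle of alpha/theta activity, short enough to resolve 0.5 s suppressions |
| `d_supp_min`   | s    | 0.5     | matches the 0.5 s monitor convention; the visual gold standard (0.5 µV for > 1 s) is reachable by setting `theta_supp = 0.5, d_supp_min = 1` |
| `d_burst_min`  | s    | 0.5     | ACNS burst criterion |
| `n_phases_min` | —    | 4       | ACNS polyphasic criterion |
| `g_max`        | s    | 30      | no numeric gap bound exists in the clinical definitions; 30 s matches the flat-EEG timescale beyond which activity is considered resumed, and it is exposed as a parameter |

Two deliberate corner-case behaviours: a waveform that never crosses its
own mean (a monotone ramp) counts 1 phase; a single positive half-cycle
counts 3 under the mean baseline (it crosses its mean twice). Both readings
agree on zero-mean oscillatory segments, which is what bursts are; the
mean-baseline rule was chosen because raw EEG segments carry DC offset.
There is no band-pass prefilter by default and no artifact rejection: the
package assumes its input is the exported, artifact-screened signal.

## Calibration and cross-validated error

`optimize_params()` is an exhaustive search over a
`theta_supp × w_env` grid (default 1–10 µV × 0.25/0.5/1.0 s) minimising
the mean squared error of the detected total BS duration against the
annotated total; `objective = "bsr"` switches the loss to squared BSR
error. Ties are broken toward the smaller threshold, then the smaller
window — the most conservative of the equivalent detectors. The search is
genuinely exhaustive; a property test asserts its argmin equals a
brute-force scan through `detect_bs()`.

`bs_calibrate()` wraps this in k-fold cross-validation (default k = 10)
stratified by anesthetic group, so that each fold preserves the
propofol/sevoflurane mix; `per_group = TRUE` instead runs two fully
independent CVs, matching the reading that the two agents are calibrated
separately. Per recording, the held-out absolute errors in BS duration (s)
and BSR (percentage points) are reported with medians and
linear-interpolation (type-7) quartiles. Because detection of one recording
never depends on another, the grid × recording error matrix is computed
once and folds merely aggregate rows; a test verifies fold parameters are
identical to refitting on the training rows only, i.e. no leakage.

## What the simulators emulate — and what they do not

`simulate_eeg()` builds background EEG as one or two fixed-frequency
oscillations plus smoothed white noise, scaled to `background_rms`
(default 15 µV): alpha (10 Hz) with slow-delta (1.5 Hz) for propofol,
theta (6 Hz) for sevoflurane, putting the periodogram peak in the
agent-typical band. Episodes are alternating suppression segments
(white noise at `suppression_rms`, default 1.5 µV) and 9 Hz tapered bursts
(`burst_amp`, default 40 µV) with identical timing on all channels and
sample-aligned ground truth. By construction every generated burst
satisfies the detector's own ACNS criteria — a self-consistency the tests
assert.

`simulate_corpus()` draws the total true suppression per recording from a
zero-inflated log-normal: propofol recordings are BS-free with probability
0.45 (non-zero totals with median 20 s), sevoflurane with probability 0.65
(median 5 s), reproducing the clinical ordering in which propofol produces
stochastically longer BS while sevoflurane patients more often have none.
The corpus default is 10-minute recordings at 178 Hz; the log-normal
medians are scaled to that length (a 2–3 h surgery would carry
proportionally longer totals), and the zero-inflation shares follow from
the observation that the median sevoflurane patient has zero BS while the
median propofol patient does not. These are declared modelling choices
calibrated qualitatively to the reported quartile structure; exact cohort
quantiles are not reproduction targets.

What passing tests on this material do **not** show: robustness to
artifacts (electrode pops, EMG, cautery), to non-stationary background
amplitude, to asynchronous per-channel suppression onset, or to the
near-threshold amplitudes of real senescent EEG. The simulator separates
suppression (≈1.5 µV) from background (≈15 µV) by an order of magnitude,
so cross-validated error bounds obtained here characterise the calibration
machinery, not clinical performance.

`simulate_cohort()` draws agent, BS presence (agent-conditional), and POD
from the logistic structure
`logit P(POD) = logit(p0) + log(1.63)·sevo + log(1.50)·bs +
log(3.80)·sevo·bs`, so the four cells have conditional odds ratios
(1, 1.50, 1.63, 9.30) relative to propofol/no-BS. Defaults: n = 265,
P(sevoflurane) = 126/265, P(BS | propofol) = 0.55,
P(BS | sevoflurane) = 0.35, baseline POD risk 0.25; age ~ N(77, 4²)
truncated at 70, ASA class ~ (3%, 44%, 51%, 2%), surgery duration
log-normal with median 2.5 h. Covariates are independent of the outcome by
default (so covariate-adjusted models remain unbiased for the cell
structure); `duration_or_per_h = 1.27` adds a centred per-hour
surgery-duration effect for regression-recovery tests.

## Cohort statistics

`incidence_table()` reports the agent × POD counts, per-arm incidences,
Pearson χ² **without** continuity correction (the uncorrected test is the
package convention; `yates = TRUE` is available), the relative risk with a
log-scale Wald CI, Cohen's h, and the achieved power of the two-proportion
z-test. The power formula thresholds with the pooled standard error under
H0 and evaluates under H1 with the unpooled one; at p₁ = p₂ it returns α
exactly, and the test suite checks it against a Monte-Carlo simulation of
the same z-test. Note that this standard formula gives ≈ 0.67 at the
published arm sizes and incidences; published power figures computed with
other software sub-procedures may differ, and no attempt is made to
emulate them.

Logistic models (`fit_pod_model()`) use `stats::glm` with the predictor
set agent + age + ASA + surgery hours + care location plus the chosen BS
representation (binary indicator, continuous BSR, raw seconds, or none),
with subgroup and measurable-BS-only variants; the dose variable in the
BS-only model defaults to `log(1 + duration)` because BS durations are
log-distributed (raw seconds by flag). Wald CIs are reported throughout,
matching the reporting style of the field; profile-likelihood CIs are out
of scope. Separation is flagged (never silently reported) by catching the
fitted-probability warning and by inflated Wald SEs; missing covariates
are handled by listwise deletion with the dropped count recorded.
`fit_interaction_model()` adds the sevoflurane × any-BS product term and
derives the four conditional ORs from coefficient linear combinations,
which makes the identity OR(sevo+BS) = OR(sevo)·OR(BS)·OR(interaction)
hold to floating-point exactness.

## Numerical choices and degenerate inputs

* Intervals are half-open and sample-aligned; interval/mask conversions
  round onsets to the grid, making mask round-trips exact.
* Run-length filtering uses `ceiling(d * fs - 1e-9)` samples so that a run
  of exactly `d` seconds is kept despite floating-point representation.
* Quartiles are type-7 (linear interpolation), stated so IQRs are
  reproducible across tools.
* An empty annotation file, a BS-free recording, and a one-point grid are
  all valid inputs with defined results; `k > n` folds, empty grids,
  single-class outcomes and empty interaction cells are errors with named
  causes.
* All randomness flows through explicit integer seeds via
  `withr::with_seed`; corpus recording *i* uses sub-seed `seed + i`, and
  the caller's RNG state is never disturbed.

## Problem sizes

The shipped test suite and the acceptance script run a 60-recording corpus
(30 per agent, 10-minute 4-channel recordings at 178 Hz) through 10-fold
stratified CV over the 30-point default grid, a 200,000-patient cohort for
interaction-model recovery, 100-replicate coverage checks at n = 1,500,
and a 1,000-replicate type-I-error check of the rank-sum wrapper — sizes
chosen so the full suite completes in about a minute on a laptop while
keeping the Monte-Carlo bounds meaningful.

## Known limitations

* The detector is offline and amplitude-based only; no spectral features,
  no streaming mode, no artifact handling.
* EDF support covers continuous 16-bit recordings with one shared sampling
  rate (what frontal monitors export); EDF+ annotations and discontinuous
  files are not parsed.
* The EEG simulator is a surrogate, not a neural-mass model; its value is
  ground truth, spectral separability of the two agents, and
  self-consistency with the detector's burst definitions.
* Cohort-dependent regression estimates from any particular clinical
  dataset are not reproducible here by design; the package reproduces the
  published contingency arithmetic exactly and everything else as
  parameter-recovery and calibration properties on synthetic data.
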