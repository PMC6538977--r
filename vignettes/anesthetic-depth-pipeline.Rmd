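---
title: "Modeling anesthetic depth from discontinuous neonatal brain activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling anesthetic depth from discontinuous neonatal brain activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Around birth, cortical activity is discontinuous: transient *active periods*
of mixed-frequency oscillations alternate with near-silent intervals. In
neonatal rodents (and in human neonates up to roughly two months of age),
general anesthetics do not produce the adult pattern of slow-wave
enhancement and fast-oscillation suppression. Instead they suppress the
*occurrence* of active periods in a dose-dependent way while leaving the
spectral content and firing structure *within* the surviving active periods
largely intact. From about four months of age the adult-like,
frequency-specific pattern emerges, and the correlation between broadband
EEG amplitude and anesthetic concentration flips sign from negative to
positive.

`anesdepth` implements the full analysis chain that quantifies these
phenomena and exploits them to predict anesthetic concentration:

1. synthetic session generators with ground truth (`gen_neonatal_session()`,
   `gen_juvenile_session()`, `gen_infant_session()`);
2. signal conditioning and infant-EEG artifact scoring (`bandpass_filter()`,
   `downsample()`, `common_average_reference()`, `amplitude_envelope()`,
   `score_epochs()`);
3. event detection (`fit_detection_threshold()`, `detect_active_periods()`,
   `detect_mua()`);
4. spectral and complexity metrics (`welch_psd()`, `modulation_index()`,
   `imaginary_coherence()`, `ppc()`, `aperiodic_slope()`,
   `sample_entropy()`, `spearman_rho()`);
5. per-minute feature engineering (`mouse_features()`, `infant_features()`);
6. the concentration predictor (`train_evaluate()`,
   `classify_anesthetized()`, `train_age_stratified()`,
   `decision_space_map()`).

## Synthetic sessions and what they emulate

The generators define the study conditions for every downstream test; their
defaults were chosen once, on realism grounds, and are exposed as
parameters.

**Neonatal mouse LFP.** The trace is a pink (`1/f`) background plus bursts
placed by a thinned Poisson process: initiations arrive at
`burst_rate_hz` (default 0.25 Hz) and are retained with probability
`dose_response(concentration)`, a stepwise dose law defaulting to
occurrence factors 1, 0.6, 0.3, 0.1 at 0, 1, 2, 3% isoflurane. Durations are
lognormal (mean 3 s, floored at 1.2 s) and events are placed sequentially
with at least 0.5 s between them, so distinct true events cannot be merged
by the detector's 200 ms rule. The defaults give a baseline occupancy of
roughly 0.4, in the range reported for discontinuous neonatal activity.
Because placement is by rejection, the *realized* occupancy ratios along the
dose ladder are compressed relative to the configured factors (about
1/0.79/0.44/0.17 at the defaults) while remaining strictly monotone; tests
of the Poisson count identity therefore use a sparse configuration where
rejection is negligible.

Bursts carry a stationary mixed-band carrier (delta/theta-alpha/beta/gamma
weights 0.4/0.3/0.2/0.1) gated by 100 ms cosine ramps — so the within-burst
spectrum is identical at every dose level by construction — and an amplitude
drawn per burst from a lognormal law (mean RMS 40 uV against a 5 uV
background; burst amplitude distributions are not constrained by reported
data, so these are free parameters). Within-burst multi-unit
spikes are placed at `spike_rate_hz` with phases drawn from a von Mises law
of concentration `spike_lock_kappa` around the theta-alpha carrier; the
sampler draws the phase first and then picks a matching time point, so the
stored spike phases follow the configured law exactly up to grid rounding.

The background exponent defaults to -1 (pink). A steeper background
concentrates in-band variance at 1-3 Hz, whose slowly wandering envelope
contradicts the near-silence of real inter-burst intervals and creates
spurious supra-threshold excursions; pink noise matches the silent-period
phenomenology. The exponent remains a parameter for users who want a
different background.

**Juvenile (continuous) mode.** The burst process is disabled; band
components cover the whole trace and each band's log10 power is scaled by
`band_dose_slopes[band] * concentration`, reproducing the adult-like delta
increase and beta/gamma decrease under anesthesia. Doubling a slope doubles
the log-power offset exactly, which is the oracle used in the tests.

**Infant EEG.** All channels share one amplitude law,
`gain = exp(amplitude_dose_slope * concentration)`, with static per-channel
gain noise (lognormal, sd 0.1) and slow per-minute amplitude jitter (sd
0.03). The slope defaults are -0.25, +0.08 and +0.25 per concentration unit
for the 0-2, 2-4 and 4-6 month groups, encoding the developmental switch;
the sign is validated against the age group. Ten 5-Hz band components
(1-50 Hz, pink-weighted) receive additional per-band slopes (zero at 0-2
months — purely broadband suppression — and a delta-up/fast-down pattern in
the older groups). Artifacts are injected into distinct 5-s epochs by
count: digitizer-rail saturation (>= 1.5 s pinned at `rail_uv`, default
400 uV), single-channel 250 uV transients, and a 60 uV common 6 Hz
component that violates the cross-channel median rule. Ground truth records
the affected epochs.

What the generators deliberately do **not** model: conductance-based
biophysics, respiration/cardiac artifacts, electrode drift, inter-regional
coupling dynamics, or non-stationary anesthetic pharmacokinetics beyond the
step schedules. Passing tests therefore demonstrate the correctness and
statistical behavior of the *analysis*, not clinical performance on real
recordings.

## Detection

**Active periods.** The detection band is 1-100 Hz (third-order Butterworth,
zero-phase). The root mean square is computed in 200 ms windows with 50%
overlap — short enough to resolve the >1 s minimum event with at least
eight points. The RMS histogram (100 bins from 0 to the maximum) is fitted
with a Gaussian restricted to the bins up to and including the modal bin,
which captures the silent-period noise floor while ignoring the burst tail;
when high-amplitude events squash the floor into the first few bins the
histogram is re-formed over three times the modal bin's upper edge so the
mode is resolved. The threshold is `mu + k_sigma * sigma` with
`k_sigma = 3.5` by default (the multiplier and RMS window are free choices of this
implementation and are exposed as configuration). Supra-threshold runs
(strict `>`) become candidate events, candidates closer than 200 ms merge,
and events lasting no more than 1 s are dropped. Event amplitude is the
peak absolute deflection of the *detection-band* trace, keeping the
amplitude statistic consistent with the band that defined the event.

**Multi-unit activity.** Spikes are local minima of the 500-5000 Hz signal
below `-5 SD` (SD over the full trace) whose topographic prominence exceeds
half the peak amplitude. The implementation scans outward from each
candidate; tests pin it to an O(n^2) brute-force scan.

## Spectral and complexity metrics

* `welch_psd()` averages periodograms of non-overlapping 1-s windows
  (1 Hz resolution). The default taper is Hamming — the common Welch
  default, which controls leakage from strong low-frequency components —
  with a rectangular option. Band power integrates the grid by trapezoid.
* `modulation_index()` is `(post - pre) / (post + pre)`, `NA` at 0/0.
* `imaginary_coherence()` estimates auto- and cross-spectra from 1-s Hann
  segments with 50% overlap (a bias/variance tradeoff independent of the
  PSD operation's non-overlap rule, which is part of the PSD's definition)
  and returns `|Im|` of the normalized cross-spectrum alongside the
  magnitude coherence that bounds it.
* `ppc()` extracts the band phase by Hilbert transform and evaluates the
  mean pairwise cosine through the identity
  `(|sum e^{i theta}|^2 - n) / (n(n-1))`, the unbiased spike-count-free
  form.
* `aperiodic_slope()` fits `log10` power on `log10` frequency over
  20-40 Hz by iteratively reweighted least squares (`MASS::rlm`),
  dropping nonpositive grid points; the per-minute wrapper
  `slope_timecourse()` applies it in 60 s bins. The recovery oracle
  synthesizes noise with *exact* spectral amplitudes and random phases
  (`one_over_f_noise(random_phase = TRUE)`, the default) with the power law
  flattened below 4 Hz: real spectra plateau at low frequency, and with
  independent 1-s windows and a rectangular taper the estimate is exactly
  deterministic, isolating the estimator from single-realization
  interference. A contiguous Gaussian trace gives the same slope with
  sampling scatter of roughly +/- 0.1-0.25 per 3-minute estimate.
* `sample_entropy()` uses template length `m = 2` (the customary default
  for physiological series), Chebyshev distance,
  tolerance `0.2 * sd` of the analyzed window, lag 1, self-matches
  excluded; `sample_entropy_profile()` applies it in 1.5 s windows to 2-Hz
  bands anchored at 1 Hz, which keeps the grid inside the EEG analysis
  range.
* `spearman_rho()` wraps the mid-rank Pearson correlation.

## Infant EEG scoring

The scoring rules operationalize three criteria stated for 5-s epochs:
signal saturation, absolute amplitude above 150 uV, and a cross-channel
median above 30 uV. Two of these need interpretation, which this package
fixes as follows: *saturation* is at least three consecutive samples pinned
at the digitizer rail value (`rail_uv`), and the *median rule* rejects an
epoch when the per-sample median across retained channels of the 1-s
amplitude envelope exceeds 30 uV at any sample. Channels whose broadband
variance falls below 1% or above 100 times the cross-channel median are
excluded automatically — a reproducible proxy for the visual rejection of
low-SNR channels. The epoch grid is anchored at t = 0 and a partial
trailing epoch is scored when at least half of it exists. A minute is
removed when its contaminated time strictly exceeds 10 s (so two bad
epochs are retained, three are not), and subjects with fewer than 20
artifact-free minutes are excluded with an explicit `subject_excluded`
condition.

## Feature engineering

Mouse tables have 15 features per region (PFC and HP, 30 columns): ten
10-Hz power bins over 1-100 Hz, the percentage of time in active periods,
the median clipped event length and event count per minute, and the median
and maximum of the 1-s amplitude envelope (amplitude summaries could be
taken from the raw trace instead; the envelope keeps mouse and human
features consistent). Labels are the nominal delivered
concentration of each 15-min block. Every column is divided by its median
over the non-anesthetized baseline minutes; a column whose baseline median
is zero is left unscaled.

Infant tables have 5 features per signal (the unfiltered trace plus ten
5-Hz bands, 55 columns): the channel-averaged median envelope amplitude and
the percentage of envelope samples in each amplitude quartile class.
Quartiles are computed once per subject on the entire channel-averaged
envelope; class membership uses half-open intervals with a closed top
class, so the four percentages always sum to 100 before normalization.
The per-band signal isolation on this path uses zero-phase spectral
masking, which is exact in band and fast on long multichannel sessions.
Labels are the mean of the 1 Hz end-tidal samples within each minute.
Normalization uses the concentration-0 minutes, falling back to the
lowest-concentration minutes for recordings started after induction. The
normalized table is invariant to any global gain on the raw signal.

## The concentration predictor

The pipeline is: quantile transform (tuned number of quantiles) ->
mutual-information feature selection (tuned percentile) -> RBF
support-vector classifier for anesthetized vs awake -> RBF support-vector
regressor for the concentration, with the classifier's *predicted label*
appended as one extra regressor input (the prediction, not the
classifier's input features, is what the regressor receives). On training rows the
appended feature is the 3-fold out-of-fold prediction, so the regressor
never sees in-sample classifier output; held-out rows get the full
classifier's prediction.

Evaluation repeats `n_iterations` (default 100) random 2/3-1/3 splits.
All hyper-parameters are re-tuned per iteration by 3-fold grid search on
the training part only, in two stages: classifier `C`/`gamma` by accuracy
first, then the remaining pipeline by regressor R^2 with the classifier's
hyper-parameters fixed; a single joint grid over both models would be
combinatorially heavier for no measured benefit. During tuning the
appended classifier feature is computed in-sample per inner fold for
tractability. Default grids: `n_quantiles` {10, 100, 1000},
`select_percentile` {25, 50, 75, 100}, `C` {0.1, 1, 10, 100}, `gamma`
{scale-heuristic, 0.01, 0.1, 1}, `epsilon` {0.01, 0.1, 0.5};
`reduced_spec_grid()` is the desk-scale subset used by the packaged
experiments. Mutual information is estimated by quantile binning (eight
bins); it is used only to *rank* features, where the estimator family is
uncritical. SVMs are libsvm via `e1071`; features reach the kernel already
quantile-mapped to [0, 1], so no additional scaling is applied.

Splits default to the level of 1-minute rows; `group_by_subject = TRUE` splits at the subject level and is the
recommended setting when assessing generalization to new individuals,
since row-level splits share subjects between train and test. Pooled
metrics (R^2, median absolute error) are computed over the concatenated
held-out predictions. One master seed fans out per-iteration seeds, so a
fixed seed reproduces splits, chosen hyper-parameters and metrics exactly.
Age stratification either trains three regressors with 2 and 4 months as
cut-offs or one model with age appended as a feature. The decision-space
map embeds the transformed feature rows with an exact t-SNE (duplicate
rows share coordinates) and paints the plane by k-nearest-neighbor
regression (k = 1, a Voronoi tessellation) on the predictions.

## Problem sizes and numerical choices

The packaged experiments run at desk scale by design: mouse sessions at
1 kHz (not the 32 kHz acquisition rate; the analysis band tops out at
100 Hz), MUA tests on 20 kHz segments, infant sessions at 256 Hz with 9
channels and 28 minutes, cohorts of 8 pups and 12 infants, 20 resampling
iterations with the reduced grid for the mouse experiment and 10 for the
infant models. Human concentration labels are treated as a dimensionless
fraction of an age-adjusted reference; the pipeline is unit-agnostic.
Ties at the detection threshold use strict `>`; the quantile transform
clips out-of-range values to the training quantile boundaries; constant
feature columns map to 0.5; a split that leaves a single training class is
redrawn (up to ten times) with the iteration's seed stream.

## Known limitations

* The generators encode monotone, memoryless dose laws; hysteresis and
  pharmacokinetic lags are not modeled, so transfer claims across
  anesthetics rest only on the shared suppression structure.
* Row-level resampling shares subjects between train and test; use the
  subject-level mode for a stricter claim.
* The binned mutual-information estimator is coarse for very small tables
  (fewer than ~30 rows per class).
* The 30 uV median rule and the saturation definition are explicit
  operationalizations of criteria that are usually applied by eye; both
  are configurable in `score_epochs()`.
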