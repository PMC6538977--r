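# anesdepth

Anesthetic-depth analysis for discontinuous neonatal brain activity:
active-period (burst) and multi-unit detection in neonatal mouse LFP,
artifact-scored envelope features for infant scalp EEG, the spectral and
complexity metrics used to characterize anesthesia at these ages, and a
resampled support-vector model that predicts anesthetic concentration from
per-minute electrophysiological features.

## Who this is for

Developmental systems neuroscientists and anesthesia researchers analyzing
immature LFP/EEG, where anesthetics act differently than in adults: instead
of slowing the EEG, they suppress the *occurrence* of discontinuous active
periods in a dose-dependent manner while the spectra and firing *within*
those periods stay largely intact. In human infants the broadband EEG
amplitude correlates negatively with end-tidal anesthetic concentration
(etAnesthetic) until ~2 months of age and positively from ~4 months — a
developmental switch any depth-of-anesthesia model for this population has
to respect.

## The model at its core

Per 1-minute bin the package computes feature vectors — for mouse LFP, band
powers in 10-Hz bins over 1–100 Hz, % time in active periods, event count
and median length, and median/max envelope amplitude per region (PFC, HP),
each normalized to its non-anesthetized baseline median; for infant EEG,
the channel-averaged median envelope amplitude and amplitude-quartile
occupancies for the broadband signal and ten 5-Hz bands. The predictor is
the pipeline

> quantile transform → mutual-information feature selection → RBF-SVM
> classifier (anesthetized vs awake; its prediction appended as a feature)
> → RBF-SVM regressor for concentration,

evaluated by n = 100 (configurable) random 2/3–1/3 splits with all
hyper-parameters re-tuned per split by 3-fold grid search, and summarized
by pooled R² and median absolute error over the held-out predictions.
Age-stratified variants (2 and 4 months as cut-offs, or one model with age
as a feature) handle the developmental switch.

A synthetic-data module generates neonatal, juvenile-continuous and infant
sessions with ground truth (true burst intervals, spike times and phases,
artifact epochs, concentration timelines), so every stage of the chain is
testable against known truth.

## Worked example

Generate a 10-minute neonatal session whose second half runs at 2%
isoflurane, detect active periods, and compare full-signal with
within-burst spectra:

```r
library(anesdepth)

params   <- neonatal_lfp_params(duration_s = 600, seed = 42)
schedule <- data.frame(start_s = c(0, 300), level = c(0, 2))
session  <- gen_neonatal_session(params, schedule)
rec      <- session$recording

thr    <- fit_detection_threshold(rec, channel = "PFC")
events <- detect_active_periods(rec, thr)
occ    <- occurrence_timecourse(events, bin_s = 300, total_s = 600)
m      <- evaluate_detection(events, session$truth$events)

psd_full  <- signal_psd(rec, "PFC", from_s = 300, to_s = 600)
psd_burst <- signal_psd(rec, "PFC", events = events, from_s = 300, to_s = 600)
```

which prints (via the calls in `?detect_active_periods` and below):

```
threshold: 4.86 uV (noise floor mu = 3.27, sigma = 0.45)
events detected: 60
occurrence 0% iso: 0.44   occurrence 2% iso: 0.23
vs ground truth: recall 1.00, mean temporal Jaccard 0.89
gamma MI, full signal: -0.32   within active periods: -0.06
```

The threshold sits 3.5 fitted standard deviations above the silent-period
RMS mode; 2% isoflurane halves the fraction of time spent in active
periods (0.44 → 0.23); and the gamma-band modulation index is strongly
negative for the full signal but near zero when power is computed only
inside detected active periods — the signature dissociation between
occurrence suppression and within-burst invariance. Cohort-level
experiments are one call each: `simulate_mouse_cohort()` +
`train_evaluate()` for the isoflurane dose ladder, and
`simulate_infant_cohort()` + `train_age_stratified()` for the age-resolved
infant model.

## Documentation

The methods vignette (`vignettes/anesthetic-depth-pipeline.Rmd`) documents
the generator assumptions, every operational definition (threshold fit,
scoring rules, metric estimators), the model pipeline and its tuning
protocol, the problem sizes used by the packaged experiments, and known
limitations.
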