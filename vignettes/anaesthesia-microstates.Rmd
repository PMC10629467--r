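---
title: "Microstates and state space descriptors of anaesthesia EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstates and state space descriptors of anaesthesia EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **eegstates**, the
assumptions behind them, the numerical choices that matter, and what the
synthetic generator does and does not emulate. It states no empirical result
beyond what the package's tests and acceptance script themselves compute.

## The analysis problem

Intraoperative multichannel EEG (19 electrodes, International 10/20 montage)
carries information about whole-brain electrical organization that bi-frontal
depth-of-anaesthesia monitors cannot see. Two complementary summaries are
computed here per EEG interval:

* **Microstates** — sub-second periods of quasi-stable scalp topography,
  grouped into four classes (A–D). Their *duration*, *frequency of
  occurrence* and *global field power* (GFP) index the stability and
  strength of large-scale network activity.
* **State space descriptors** — *sigma* (total variance, µV²), *phi*
  (generalized frequency, Hz) and *omega* (spatial complexity,
  dimensionless) summarize the trajectory of the multichannel signal through
  channel space.

Both families are tracked over *anaesthesia duration* (minutes since
induction), separately for *suppression* EEG (amplitude < 10 µV, a marker of
excessively deep anaesthesia) and normal-voltage EEG, and compared between
patients who later do or do not develop postoperative delirium (POD).

## Preprocessing

* **Filter.** 2–20 Hz band-pass, 4th-order Butterworth applied
  forward–backward (zero phase). Only the band is scientifically fixed; the
  realization is our choice. Channels are padded by odd reflection
  (one low-cut period, `fs/low` samples) before `filtfilt` so edge
  transients and DC offsets do not leak into short epochs.
* **Reference.** Average reference (per-sample channel mean subtracted);
  idempotent, and it commutes with the per-channel filter — tested.
* **Sampling rate.** Acquisition systems run in the kHz range; analysis
  uses 250 Hz (4 ms microstate resolution, standard in this literature).
  `resample_signal()` converts between integer rates; the generator emits
  250 Hz directly.
* **Suppression rule.** Peak-to-peak amplitude per channel, maximised over
  channels, strictly below 10 µV, measured on the filtered signal — a
  deterministic reading of "amplitude < 10 µV", and scale-monotone
  (attenuating an epoch can never un-suppress it).
* **Intervals.** Epochs are grouped greedily in time order, separately per
  suppression status, into sets of ≤ 24 epochs; a set is closed when the
  next epoch starts > 15 min after the set's first epoch (sampling aimed at
  one interval every ~30 min). Sets with fewer than 2 epochs are dropped —
  statistics on a single epoch are degenerate. Both bounds are arguments.

## Microstate segmentation

Maps at strict local maxima of the GFP time series (first/last samples
excluded) enter a **polarity-invariant modified k-means**: maps are
GFP-normalized (so high-amplitude epochs do not dominate — the original
plugin's behaviour is not documented, this is our choice), each map is
assigned to the class map maximising squared spatial correlation, and each
class map is updated as the first principal eigenvector of the outer-product
sum of its assigned maps. Convergence: assignments unchanged or explained
variance gain < 1e-6; 20 seeded random restarts by default, best explained
variance wins. Ties in assignment go to the lowest class index; eigenvector
signs are fixed by making the largest-magnitude channel positive; classes
that attract no maps are flagged degenerate rather than re-seeded.

Hierarchical averaging follows the study's scheme: per-interval solutions →
time-conditional group means (cells with < 2 solutions are excluded) → grand
mean. Alignment searches all 24 label permutations exhaustively (exact and
cheap for four classes) and flips polarities to maximise within-class shared
variance; the average is re-normalized and refined in a second pass.

Grand-mean classes are labelled A–D by the permutation maximising the summed
|spatial correlation| against template maps, ties broken lexicographically.
The packaged templates (`inst/extdata/templates_1020_synthetic.csv`) are
*synthetic* approximations of the canonical topographies built from idealized
10/20 electrode geometry — published normative maps are not redistributed;
users with montage-matched normative maps should supply them.

## Quantifiers

Back-fitting labels every GFP-peak sample with the best-fitting grand-mean
class (polarity-blind) and assigns every other sample the label of the
temporally nearest peak; exact distance ties go to the earlier peak, making
segment boundaries deterministic. Runs touching either epoch edge are
truncated — their true extent is unobserved — and excluded. Per interval and
class:

* duration = mean retained-run length × 1000/fs (ms);
* occurrence = retained-run count / total epoch seconds of the interval.
  The denominator deliberately uses the *full* epoch time rather than time
  net of truncated runs: it is simple, identical across classes, and keeps
  the coverage identity Σ(occurrence × duration) ≤ 1000 ms/s interpretable;
* GFP = mean over runs of the run's mean per-sample GFP (the mean, not the
  peak — the choice is not documented in the source literature).

No minimum-duration smoothing is applied before segmentation; whether the
original analysis smoothed labels is unknown, and smoothing would bias the
duration recovery tests.

A class absent from an interval yields *missing* duration/GFP (not zero — a
zero duration is undefined, not observed) and occurrence 0; missing cells
are dropped listwise by the models, never imputed.

## State space descriptors

The spatial PCA decomposes the channel second-moment matrix over the epoch;
average-referenced data are confined to a (k−1)-dimensional subspace, so the
smallest of the k eigenvalues is numerically zero (asserted in tests).

* **sigma** = Σλ, the covariance trace: quadratic in amplitude, invariant to
  channel-space rotations.
* **phi** uses the classic generalized-frequency form
  `(1/2π)·sqrt(Σ‖Δu‖²·fs² / Σ‖u‖²)` with a forward first difference and no
  smoothing. A looser prose reading ("sum of the first derivative …
  normalized by sigma") would not carry frequency units; the closed form
  returns *f* for a pure sinusoid at *f* Hz up to the discretization factor
  `sin(πf/fs)/(πf/fs)` (≈ 0.3% at 10 Hz, 250 Hz) — within the 2% tolerance
  the tests assert.
* **omega** is the *antilog* of the Shannon entropy of the normalized
  spectrum, required for the stated 1-to-k range; natural logs are used
  internally (the base cancels in the antilog). Eigenvalues below
  1e-12 × λmax are clamped to zero before the entropy, so rank-1 data give
  omega = 1 exactly in floating point.

Per interval, descriptors are arithmetic means over the set's epochs.

## Trend models

Each response is fitted by `lmerTest::lmer` (REML, bobyqa) with fixed part
`duration × suppression × POD` (× class for quantifiers, stacked long with
class as a factor), additive covariates (age, sex, MMSE band, ASA band,
surgical site, anaesthetic type, randomization arm), and a random intercept
per patient. The random-effects structure is not documented in the source
literature; a per-patient random duration slope is available as an option
but not the default — with ≤ ~10 intervals per patient it is frequently
singular. References are no POD, no suppression, duration 0, class A.

Term tests use F-statistics with Satterthwaite degrees of freedom; the
`ddf` argument of `anova_table()` exposes the other conventions because the
original analysis' `aov`-based testing may differ and neither is uniquely
defensible. Per-cell duration slopes are computed as model-matrix
difference contrasts — the design row at duration 1 minus the row at
duration 0 in the requested cell, covariates held fixed — which reproduces
the published coefficient-sum recipes exactly (the reference cell returns
the bare duration coefficient; the Supp⁺|POD⁺ descriptor cell the four-term
sum) and yields Satterthwaite CIs via `contest1D`. Predicted trajectories
are Wald confidence bands on the fixed-effects surface with covariates at
reference levels / sample means; durations outside the observed range are
flagged, not refused.

If preprocessing leaves a single suppression status (e.g. threshold 0), the
factor is dropped and the models degrade to the duration × POD design;
requesting a suppression cell from such a model is an explicit error.

## TANOVA and t-maps

The TANOVA is run on each patient's first non-suppression and first
suppression interval maps (time omitted, as in the source design), after
GFP-normalizing every map. The tool originally used for this test is closed
source and its statistic is not published; we use the standard
randomization construction: for an effect, cell-mean topographies are
residualized by marginal-mean inclusion–exclusion, the statistic is the RMS
over effect cells of the residual map's GFP (for a two-level effect this is
monotone-equivalent to the GFP of the difference of the two cell means),
and the null is built by permuting within-subject condition labels per
subject and/or POD labels across subjects. p = (count ≥ observed + 1) /
(permutations + 1), so the attainable resolution is 1/(n+1). Between-subject
effects require ≥ 2 patients per group. Channel-wise t-maps are paired t
statistics per electrode (Welch for unpaired designs).

## The synthetic generator

`simulate_cohort()` emulates the study conditions: 19 channels, four
classes, 2.5-s epochs at 250 Hz in 24-epoch intervals spaced ~30 min, POD in
29% of patients and suppression in a third of intervals (assigned as exact
counts, not Bernoulli draws, so small cohorts keep the design), patient
covariates drawn from distributions mirroring an older surgical population.
Within an epoch, microstate segments follow a gamma length law (shape 2,
mean 100 ms — the literature quotes 80–120 ms but no law, so the shape is
configurable) truncated at one sample; each segment projects one class map
amplitude-modulated by a 10 Hz carrier (inside the 2–20 Hz band, so
filtering preserves structure) with per-segment lognormal amplitude and
random phase; white noise is scaled by the configured SNR. Suppression
epochs keep the identical microstate sequence and are rescaled as a whole to
a 5 µV peak-to-peak amplitude — microstates are analysed *within*
suppression, so structure must survive. Group trends are injected on the
*generating parameters* (segment duration, map gain) per
(suppression × POD) cell, never on computed outputs, so downstream recovery
is a genuine test.

What the generator does **not** emulate: burst fragments around suppression
(bursts were excluded from the emulated analyses and their amplitude law is
unreported), operating-room artefacts (electrocautery, movement), anaesthetic
pharmacology, drifting electrode impedances, and spatially correlated noise.
Passing round-trip tests therefore demonstrate the *pipeline's* correctness
under controlled conditions, not robustness to real operating-room data.

`simulate_trend_data()` generates quantifier/descriptor record tables
directly at the parameter level (random patient intercept + per-cell linear
trend + residual noise). It exists to calibrate the statistical stage across
hundreds of seeded replicates, which would be prohibitively slow through
waveform synthesis and is statistically equivalent for that purpose.

## Problem sizes and reproducibility

The shipped tests use scaled-down designs chosen to exercise every code
path at comfortable precision: clustering and duration recovery on 24–48
epochs at SNR 20, the end-to-end pipeline on 6 patients × 3 intervals × 6
epochs, and statistical calibration on 200 replicates of 24-patient record
tables (LMM) and 12-subject map arrays with 99 permutations (TANOVA). All
randomness flows through explicit seeds; rerunning the pipeline with the
same configuration writes byte-identical tables, and every output table
carries the MD5 hash of its configuration.

## Known limitations

* Four classes and 19 channels are assumptions of the emulated design, not
  recommendations; the code accepts generic class/channel counts but the
  packaged templates are 19-channel.
* The TANOVA permutation scheme for interactions (permuting the involved
  within-factor cells jointly) is one of several defensible conventions.
* Cohort persistence uses plain-text CSV/JSON; these files are large for
  long recordings and are meant for synthetic cohorts and interchange, not
  archival of clinical EEG.
* Real-data ingestion expects epochs already cut and artefact-screened;
  automatic artefact rejection is out of scope (the emulated workflow used
  visual inspection).
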