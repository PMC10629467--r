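# eegstates

Whole-brain EEG analysis during general anaesthesia: microstate segmentation
and quantifiers, Wackermann state space descriptors, suppression-EEG
handling, topographic randomization statistics, and mixed-effects trend
models of how these quantities evolve with anaesthesia duration in patients
who do or do not later develop postoperative delirium (POD).

The package is written for clinical neurophysiologists and biostatisticians
working with multichannel (10/20 montage) intraoperative EEG. Because such
recordings are rarely shareable, a synthetic cohort generator with full
ground truth (class maps, per-sample state sequences, suppression intervals,
group-by-time trends on the generating parameters) makes every stage of the
pipeline testable end to end.

## What it computes

**Preprocessing.** Continuous recordings are band-pass filtered 2–20 Hz
(4th-order Butterworth, forward–backward, zero phase), re-referenced to the
average reference, cut into 2.5-s epochs, and grouped into intervals of at
most 24 epochs of a common suppression status. *Suppression EEG* is a period
of low voltage with amplitude < 10 µV (peak-to-peak, maximised over
channels). Each interval's *anaesthesia duration* is the mean time since
induction of its member epochs.

**Microstates.** The global field power of an average-referenced map
*v* is its spatial standard deviation,
`GFP(v) = sqrt(mean((v - mean(v))^2))`. Maps at GFP peaks are clustered by a
polarity-invariant modified k-means (class update = first principal
eigenvector of the assigned maps' outer-product sum) into four class maps;
per-interval solutions are averaged hierarchically (interval → group × time
→ grand mean) with exhaustive permutation/polarity alignment, and labelled
A–D against packaged synthetic approximations of the canonical templates.
Back-fitting assigns every GFP peak to the class with maximal |spatial
correlation| and interpolates other samples from the nearest peak; runs
touching an epoch edge are discarded as truncated. Per interval and class
the pipeline reports mean **duration** (ms), **frequency of occurrence**
(1/s) and mean **GFP** (µV).

**State space descriptors.** From the spatial PCA of each epoch (channel
covariance eigenvalues λ₁ ≥ … ≥ λ_k):

- **sigma** = Σλᵢ — total EEG variance (µV²),
- **phi** = (1/2π) · sqrt(Σₜ‖u(t+1) − u(t)‖²·fs² / Σₜ‖u(t)‖²) — generalized
  frequency (Hz),
- **omega** = exp(−Σ pᵢ ln pᵢ), pᵢ = λᵢ/Σλ — spatial complexity, a
  lower-bound estimate of the number of uncorrelated processes, ranging from
  1 (rank-1 data) to k (equal eigenvalues).

**Statistics.** Each quantifier/descriptor is modelled by a
covariate-adjusted linear mixed-effects model (REML, random intercept per
patient) with the interaction anaesthesia duration × suppression × POD
(× microstate class for quantifiers), references at no POD / no suppression /
duration 0. Per-cell duration slopes (e.g. the Supp⁺|POD⁺ slope = duration +
duration×suppression + duration×POD + duration×suppression×POD) come with
Satterthwaite CIs and p-values; predicted trajectories are emitted as
plot-ready tables. A topographic ANOVA (TANOVA) permutation test compares
first-interval topographies across class, suppression and POD, and
channel-wise t-maps localize condition differences.

## Worked example

```r
library(eegstates)

cfg <- pipeline_config(
  seed = 11,
  simulation   = list(n_patients = 6, intervals_per_patient = 3, epochs_per_set = 6),
  preprocessing = list(epochs_per_set = 6),
  microstates  = list(restarts = 5),
  stats        = list(n_permutations = 199)
)
res <- run_pipeline(cfg)   # add out_dir = "results/" to write CSV tables

head(res$descriptors[, c("patient_id", "mean_time", "suppression",
                         "sigma", "phi", "omega")], 4)
#>   patient_id mean_time suppression sigma  phi omega
#> 1       P001      32.2       FALSE   525 10.2  3.77
#> 2       P001      57.6        TRUE     3 10.2  3.59
#> 3       P001      92.7       FALSE   474 10.2  3.75
#> 4       P002      30.4       FALSE   520 10.1  3.86
```

One row per EEG interval: suppression intervals have tiny total variance
(sigma, µV²) because suppression epochs sit below the 10 µV threshold; the
generalized frequency stays near the 10 Hz carrier of the generator; omega
near 3.8 reflects the four underlying microstate generators plus noise.

```r
subset(res$contrasts, response == "omega")[, c("pod", "suppression",
                                               "estimate", "lower", "upper", "p")]
#>    pod suppression estimate   lower  upper     p
#>  FALSE       FALSE  0.00054 -0.0023 0.0034 0.659
#>   TRUE       FALSE  0.00079 -0.0027 0.0043 0.603
#>  FALSE        TRUE -0.00542 -0.0174 0.0066 0.312
#>   TRUE        TRUE  0.39343 -0.0879 0.8748 0.092
```

Per-cell slopes of omega per minute of anaesthesia with 95% CIs — here the
cohort was generated with zero injected trends, and all four cells are
compatible with a flat course.

```r
res$tanova
#>                 effect observed     p n_permutations
#>                  class 0.867896 0.005            199
#>            suppression 0.003504 0.740            199
#>                    pod 0.003757 0.125            199
#>      class:suppression 0.004840 1.000            199
#>              class:pod 0.005815 1.000            199
#>        suppression:pod 0.003601 0.415            199
#>  class:suppression:pod 0.006970 1.000            199
```

The TANOVA on first-interval maps detects the (real) main effect of
microstate class and nothing else — as it should on a null cohort.

## Documentation

The methods vignette (`vignettes/anaesthesia-microstates.Rmd`) describes the
models, the synthetic generator and its limits, numerical choices, and the
design decisions behind the defaults.
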