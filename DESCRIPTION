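Package: eegstates
Title: Microstate and State Space Analysis of Multichannel Anaesthesia EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-brain electrical activity in
    multichannel EEG recorded during general anaesthesia. Provides
    preprocessing (band-pass filtering, average referencing, suppression
    detection, interval assembly), polarity-invariant microstate
    segmentation (modified k-means on global field power peaks, hierarchical
    map averaging, template labelling), microstate quantifiers (duration,
    frequency of occurrence, global field power), Wackermann state space
    descriptors (sigma, phi, omega), topographic randomization statistics
    (TANOVA, channel-wise t-maps), and covariate-adjusted linear
    mixed-effects trend models of the quantifiers and descriptors over
    anaesthesia duration. A synthetic cohort generator with known ground
    truth (class maps, state sequences, suppression intervals, group-by-time
    trends) makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
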