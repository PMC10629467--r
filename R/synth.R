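#' Simulation configuration
#'
#' Bundles the generating parameters of the synthetic microstate EEG
#' generator. Defaults mirror the study conditions the package targets:
#' 19-channel 10/20 EEG, four microstate classes, 2.5-s epochs grouped into
#' 24-epoch intervals, mean microstate duration 100 ms (the literature range
#' is 80-120 ms), an amplitude-modulated 10 Hz carrier inside the 2-20 Hz
#' analysis band, and suppression epochs rescaled to a 5 microvolt peak
#' amplitude (below the 10 microvolt suppression threshold).
#'
#' @param n_channels Electrode count (default 19).
#' @param n_classes Microstate classes (default 4); must be at most
#'   `n_channels - 1` because average-referenced maps span a (k-1)-dim space.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param epoch_length Epoch length in seconds (default 2.5);
#'   `epoch_length * sampling_rate` must be an integer.
#' @param epochs_per_set Epochs per interval (default 24).
#' @param mean_state_duration Mean microstate segment duration in ms
#'   (default 100).
#' @param duration_shape Gamma shape of the segment-length law (default 2).
#' @param carrier_freq Carrier frequency in Hz (default 10).
#' @param snr Ratio of template signal sd to noise sd (default 5).
#' @param gain Map amplitude scale in microvolts (default 30).
#' @param suppression_amplitude Peak-to-peak amplitude that suppression
#'   epochs are rescaled to, microvolts (default 5).
#' @param seed Integer seed driving all cohort randomness.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_channels = 19L, n_classes = 4L,
                              sampling_rate = 250, epoch_length = 2.5,
                              epochs_per_set = 24L,
                              mean_state_duration = 100, duration_shape = 2,
                              carrier_freq = 10, snr = 5, gain = 30,
                              suppression_amplitude = 5, seed = 1L) {
  if (!is_count(n_channels, 2L)) stop("`n_channels` must be a count >= 2", call. = FALSE)
  if (!is_count(n_classes) || n_classes > n_channels - 1L) {
    stop("`n_classes` must satisfy 1 <= n_classes <= n_channels - 1", call. = FALSE)
  }
  if (!is_number(mean_state_duration) || mean_state_duration <= 0) {
    stop("`mean_state_duration` must be positive", call. = FALSE)
  }
  n_samples <- epoch_length * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("`epoch_length * sampling_rate` must be an integer sample count", call. = FALSE)
  }
  structure(
    list(n_channels = as.integer(n_channels), n_classes = as.integer(n_classes),
         sampling_rate = sampling_rate, epoch_length = epoch_length,
         epochs_per_set = as.integer(epochs_per_set),
         mean_state_duration = mean_state_duration,
         duration_shape = duration_shape, carrier_freq = carrier_freq,
         snr = snr, gain = gain,
         suppression_amplitude = suppression_amplitude,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Random template microstate class maps
#'
#' Draws `n_classes` average-referenced, unit-norm, mutually orthogonal
#' channel maps (orthogonality implies zero pairwise spatial correlation,
#' well below the 0.7 distinctness bound). These serve as ground-truth class
#' maps for the generator; use [normative_templates()] for canonical-looking
#' topographies.
#'
#' @param n_channels Electrode count.
#' @param n_classes Number of maps; at most `n_channels - 1`.
#' @param seed Optional integer seed.
#' @return Matrix `n_classes x n_channels`; rows sum to zero and have unit
#'   Euclidean norm.
#' @export
make_template_maps <- function(n_channels, n_classes, seed = NULL) {
  if (!is_count(n_channels, 2L)) stop("`n_channels` must be a count >= 2", call. = FALSE)
  if (!is_count(n_classes) || n_classes > n_channels - 1L) {
    stop(sprintf("%d average-referenced channels span only %d dimensions",
                 n_channels, n_channels - 1L), call. = FALSE)
  }
  with_seed(seed, {
    g <- matrix(rnorm(n_channels * n_classes), n_channels, n_classes)
    g <- g - matrix(colMeans(g), n_channels, n_classes, byrow = TRUE)  # zero-sum
    q <- qr.Q(qr(g))                                                    # orthonormal
    m <- t(q[, seq_len(n_classes), drop = FALSE])
    m <- m - rowMeans(m)   # guard: QR keeps the zero-sum subspace, enforce exactly
    m <- unit_rows(m)
    t(apply(m, 1L, canonical_sign))
  })
}

# Draw a microstate state sequence of total length n_samples.
# Returns list(states = per-sample class index, segments = rle-style table).
draw_state_sequence <- function(n_samples, n_classes, mean_dur_samples,
                                shape) {
  states <- integer(0)
  cls <- sample.int(n_classes, 1L)
  lens <- integer(0)
  clss <- integer(0)
  while (length(states) < n_samples) {
    len <- max(1L, round(rgamma(1L, shape = shape,
                                scale = mean_dur_samples / shape)))
    states <- c(states, rep.int(cls, len))
    lens <- c(lens, len)
    clss <- c(clss, cls)
    cls <- if (n_classes > 1L) {
      sample(setdiff(seq_len(n_classes), cls), 1L)
    } else 1L
  }
  list(states = states[seq_len(n_samples)],
       segments = data.frame(class = clss, length = lens))
}

#' Simulate one microstate-structured EEG epoch
#'
#' Builds a multichannel epoch as a sequence of microstate segments: within
#' each segment the scalp topography is one fixed class map, amplitude
#' modulated by a carrier sinusoid (continuous phase, per-segment random
#' amplitude and phase offset), plus white noise scaled by the configured
#' signal-to-noise ratio. Segment lengths follow a gamma law (shape
#' `duration_shape`, mean `mean_state_duration`), truncated at one sample.
#' Suppression epochs keep the identical microstate sequence and are rescaled
#' as a whole so the maximal peak-to-peak channel amplitude equals
#' `suppression_amplitude`.
#'
#' Randomness is drawn from the current RNG stream; seed the caller (or use
#' [simulate_cohort()]) for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param class_maps Matrix `n_classes x n_channels` of unit-norm maps, e.g.
#'   from [make_template_maps()].
#' @param suppression Simulate a suppression epoch (default `FALSE`).
#' @param onset Onset in minutes from induction, stored on the epoch.
#' @param forced_class Optional single class index generating the whole epoch
#'   (used for noise-free limit checks).
#' @param mean_state_duration,gain Optional overrides of the config values
#'   (the cohort generator drifts these with anaesthesia time).
#' @return List with `epoch` (an [eeg_epoch()]) and `states` (the generating
#'   per-sample class indices, 1-based).
#' @export
simulate_epoch <- function(config, class_maps, suppression = FALSE,
                           onset = 0, forced_class = NULL,
                           mean_state_duration = NULL, gain = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  class_maps <- as_map_matrix(class_maps)
  if (ncol(class_maps) != config$n_channels) {
    stop("class map channel count does not match the config", call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- round(config$epoch_length * fs)
  mean_dur <- max(mean_state_duration %||% config$mean_state_duration, 4)
  gain <- max(gain %||% config$gain, 0.1)

  if (is.null(forced_class)) {
    seq_ <- draw_state_sequence(n, nrow(class_maps),
                                mean_dur / 1000 * fs, config$duration_shape)
  } else {
    seq_ <- list(states = rep.int(as.integer(forced_class), n),
                 segments = data.frame(class = as.integer(forced_class),
                                       length = n))
  }
  states <- seq_$states
  tt <- (seq_len(n) - 1L) / fs
  # per-segment amplitude and phase offset, continuous carrier
  seg_id <- rep(seq_len(nrow(seq_$segments)), times = seq_$segments$length)[seq_len(n)]
  amps <- exp(rnorm(nrow(seq_$segments), mean = 0, sd = 0.3))
  phases <- runif(nrow(seq_$segments), 0, 2 * pi)
  carrier <- amps[seg_id] * sin(2 * pi * config$carrier_freq * tt + phases[seg_id])
  signal_mat <- t(class_maps[states, , drop = FALSE]) * rep(gain * carrier,
                                                            each = config$n_channels)
  noise_sd <- sd(signal_mat) / config$snr
  data <- signal_mat + matrix(rnorm(length(signal_mat), sd = noise_sd),
                              nrow = config$n_channels)
  if (suppression) {
    ptp <- max(apply(data, 1L, function(ch) diff(range(ch))))
    if (ptp > 0) data <- data * (config$suppression_amplitude / ptp)
  }
  ep <- eeg_epoch(data, fs, onset = onset, suppression = suppression,
                  channel_labels = if (config$n_channels == 19L) channels_1020())
  list(epoch = ep, states = states)
}

# Patient covariates mirroring the study population: older surgical patients,
# about 40% female, MMSE >= 24, roughly half ASA III-IV, a third
# abdominal/thoracic surgery, a third TIVA.
simulate_patient_meta <- function(n_patients, pod_fraction) {
  pod <- rep(FALSE, n_patients)
  pod[sample.int(n_patients, round(pod_fraction * n_patients))] <- TRUE
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    age = pmax(60, round(rnorm(n_patients, 71, 7))),
    sex = sample(c("female", "male"), n_patients, TRUE, prob = c(0.4, 0.6)),
    mmse_band = sample(c("24-27", "28-29", "30"), n_patients, TRUE,
                       prob = c(0.25, 0.35, 0.4)),
    asa_band = sample(c("I-II", "III-IV"), n_patients, TRUE, prob = c(0.48, 0.52)),
    surgical_site = sample(c("abdomen/thorax", "other"), n_patients, TRUE,
                           prob = c(0.34, 0.66)),
    anaesthetic = sample(c("TIVA", "inhalation"), n_patients, TRUE,
                         prob = c(0.36, 0.64)),
    randomization = sample(c("open", "blinded"), n_patients, TRUE),
    pod = pod,
    stringsAsFactors = FALSE
  )
}

cell_name <- function(suppression, pod) {
  paste0("supp", as.integer(suppression), "_pod", as.integer(pod))
}

#' Zero group effects
#'
#' Convenience constructor for the `group_effects` argument of
#' [simulate_cohort()]: per-(suppression x POD)-cell linear drifts, per
#' minute of anaesthesia, of the two generating parameters — microstate
#' duration (ms/min) and map gain (relative change/min).
#'
#' @return Named list with `duration` and `gain` slope vectors over cells
#'   `supp0_pod0`, `supp1_pod0`, `supp0_pod1`, `supp1_pod1`, all zero.
#' @export
zero_group_effects <- function() {
  cells <- c("supp0_pod0", "supp1_pod0", "supp0_pod1", "supp1_pod1")
  list(duration = setNames(rep(0, 4), cells),
       gain = setNames(rep(0, 4), cells))
}

#' Simulate a synthetic patient cohort
#'
#' Generates a full cohort of microstate-structured EEG with known ground
#' truth: shared class maps, per-epoch state sequences, suppression
#' intervals, patient covariates, and group-by-time trends injected on the
#' generating parameters (segment duration, map gain) — not on computed
#' outputs — so downstream recovery is a genuine test. POD status and
#' suppression intervals are assigned to exactly `round(fraction * n)` units.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param n_patients Number of patients (default 20).
#' @param pod_fraction Fraction of patients who later develop POD (default
#'   0.29, the study's observed rate).
#' @param intervals_per_patient Intervals per patient (>= 2; trends are
#'   unidentifiable from one interval).
#' @param suppression_fraction Fraction of each patient's intervals that are
#'   suppression intervals (default 1/3, matching the study's 294/885).
#' @param group_effects Per-cell generating-parameter drifts; see
#'   [zero_group_effects()].
#' @param interval_spacing Minutes between consecutive interval centres
#'   (default 30).
#' @return An object of class `synthetic_cohort`: list with `patients` (each
#'   with `meta` and a time-ordered flat list of [eeg_epoch()]s), `meta`
#'   (cohort covariate table), `truth` (class maps, per-epoch state
#'   sequences, per-interval generating parameters, group effects) and
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            n_patients = 20L,
                            pod_fraction = 0.29,
                            intervals_per_patient = 8L,
                            suppression_fraction = 1 / 3,
                            group_effects = zero_group_effects(),
                            interval_spacing = 30) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_count(n_patients)) stop("`n_patients` must be a count", call. = FALSE)
  if (pod_fraction < 0 || pod_fraction > 1 ||
      suppression_fraction < 0 || suppression_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is_count(intervals_per_patient, 2L)) {
    stop("`intervals_per_patient` must be >= 2: a trend is unidentifiable from one interval",
         call. = FALSE)
  }
  with_seed(config$seed, {
    class_maps <- make_template_maps(config$n_channels, config$n_classes)
    meta <- simulate_patient_meta(n_patients, pod_fraction)
    patients <- vector("list", n_patients)
    truth_states <- list()
    interval_rows <- list()
    for (i in seq_len(n_patients)) {
      n_supp <- round(suppression_fraction * intervals_per_patient)
      supp_idx <- if (n_supp > 0) {
        sample(seq_len(intervals_per_patient), n_supp)
      } else integer(0)
      epochs <- list()
      states_i <- list()
      for (j in seq_len(intervals_per_patient)) {
        supp <- j %in% supp_idx
        centre <- interval_spacing * j + runif(1, -5, 5)
        cell <- cell_name(supp, meta$pod[i])
        dur_j <- config$mean_state_duration +
          group_effects$duration[[cell]] * centre
        gain_j <- config$gain * (1 + group_effects$gain[[cell]] * centre)
        onsets <- centre + (seq_len(config$epochs_per_set) -
                              (config$epochs_per_set + 1) / 2) *
          config$epoch_length / 60
        for (o in onsets) {
          sim <- simulate_epoch(config, class_maps, suppression = supp,
                                onset = o, mean_state_duration = dur_j,
                                gain = gain_j)
          epochs[[length(epochs) + 1L]] <- sim$epoch
          states_i[[length(states_i) + 1L]] <- sim$states
        }
        interval_rows[[length(interval_rows) + 1L]] <- data.frame(
          patient_id = meta$patient_id[i], interval = j, mean_time = centre,
          suppression = supp, true_duration_ms = dur_j, true_gain = gain_j)
      }
      patients[[i]] <- list(meta = meta[i, ], epochs = epochs)
      truth_states[[meta$patient_id[i]]] <- states_i
    }
    structure(
      list(patients = patients, meta = meta,
           truth = list(class_maps = class_maps,
                        states = truth_states,
                        intervals = do.call(rbind, interval_rows),
                        group_effects = group_effects),
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_ep <- sum(vapply(x$patients, function(p) length(p$epochs), integer(1)))
  cat(sprintf("<synthetic_cohort> %d patients (%d POD), %d epochs, %d channels @ %g Hz\n",
              length(x$patients), sum(x$meta$pod), n_ep,
              x$config$n_channels, x$config$sampling_rate))
  invisible(x)
}

#' Simulate quantifier / descriptor record tables with known trends
#'
#' Generates per-interval response records directly at the ground-truth
#' parameter level (random patient intercept + per-cell linear time trend +
#' residual noise), bypassing waveform synthesis. This is the generator used
#' to calibrate the statistical stage: type-I error under zero slopes, and
#' sign recovery of injected per-cell slopes, across many seeded replicates.
#'
#' @param response Name of the response column (e.g. `"omega"`).
#' @param kind `"descriptor"` (one record per interval) or `"quantifier"`
#'   (one record per interval and microstate class, adding a `class` factor).
#' @param n_patients,intervals_per_patient,suppression_fraction,pod_fraction
#'   Design sizes; see [simulate_cohort()].
#' @param baseline Response value at duration 0 in the reference cell.
#' @param slopes Per-cell slopes per minute: for `"descriptor"` a named
#'   vector over `supp0_pod0 ... supp1_pod1`; for `"quantifier"` a 4 x
#'   n_classes matrix (cells x classes).
#' @param n_classes Classes for `"quantifier"` tables (default 4).
#' @param sd_patient SD of the random patient intercept.
#' @param sd_resid Residual SD.
#' @param interval_spacing Minutes between interval centres (default 30).
#' @param seed Optional integer seed.
#' @return Long-format `data.frame` joining records to patient covariates,
#'   ready for [fit_trend_model()].
#' @export
simulate_trend_data <- function(response = "omega",
                                kind = c("descriptor", "quantifier"),
                                n_patients = 24L, intervals_per_patient = 8L,
                                suppression_fraction = 0.5,
                                pod_fraction = 0.29,
                                baseline = 10, slopes = NULL,
                                n_classes = 4L,
                                sd_patient = 1, sd_resid = 1,
                                interval_spacing = 30, seed = NULL) {
  kind <- match.arg(kind)
  cells <- c("supp0_pod0", "supp1_pod0", "supp0_pod1", "supp1_pod1")
  if (is.null(slopes)) {
    slopes <- if (kind == "descriptor") {
      setNames(rep(0, 4), cells)
    } else {
      matrix(0, 4, n_classes, dimnames = list(cells, microstate_labels(n_classes)))
    }
  }
  with_seed(seed, {
    meta <- simulate_patient_meta(n_patients, pod_fraction)
    u <- rnorm(n_patients, 0, sd_patient)
    rows <- list()
    for (i in seq_len(n_patients)) {
      n_supp <- round(suppression_fraction * intervals_per_patient)
      supp_idx <- if (n_supp > 0) sample(seq_len(intervals_per_patient), n_supp) else integer(0)
      for (j in seq_len(intervals_per_patient)) {
        supp <- j %in% supp_idx
        tt <- interval_spacing * j + runif(1, -5, 5)
        cell <- cell_name(supp, meta$pod[i])
        if (kind == "descriptor") {
          y <- baseline + slopes[[cell]] * tt + u[i] + rnorm(1, 0, sd_resid)
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = meta$patient_id[i], mean_time = tt,
            suppression = supp, value = y)
        } else {
          for (k in seq_len(n_classes)) {
            y <- baseline + slopes[cell, k] * tt + u[i] + rnorm(1, 0, sd_resid)
            rows[[length(rows) + 1L]] <- data.frame(
              patient_id = meta$patient_id[i], mean_time = tt,
              suppression = supp, class = microstate_labels(n_classes)[k],
              value = y)
          }
        }
      }
    }
    tab <- do.call(rbind, rows)
    names(tab)[names(tab) == "value"] <- response
    merge(tab, meta, by = "patient_id", sort = FALSE)
  })
}
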