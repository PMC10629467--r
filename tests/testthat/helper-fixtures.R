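# Shared fixtures, all built in code.

# Multichannel sinusoid: every channel a scalar multiple of sin(2*pi*f*t).
sinusoid_epoch <- function(freq = 10, fs = 250, seconds = 2.5, n_channels = 19,
                           weights = NULL, noise_sd = 0) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  w <- weights %||% seq(-1, 1, length.out = n_channels)
  x <- outer(w, sin(2 * pi * freq * t))
  if (noise_sd > 0) x <- x + matrix(rnorm(length(x), sd = noise_sd), nrow(x))
  average_reference(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Orthogonal average-referenced unit-norm maps on n channels.
orthogonal_maps <- function(n_channels, n_classes, seed = 1) {
  make_template_maps(n_channels, n_classes, seed = seed)
}

# A set of GFP-peak maps pooled from simulated epochs (filtered, referenced).
pooled_peak_maps <- function(config, class_maps, n_epochs, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_epochs), function(i) {
    se <- simulate_epoch(config, class_maps)
    ep <- average_reference(bandpass_filter(se$epoch))
    pk <- find_gfp_peaks(ep)
    t(ep$data[, pk, drop = FALSE])
  }))
}

# Tiny epochs with prescribed GFP-peak structure on 4 channels: column j is
# amplitude[j] * map_of(class_at[j]); peaks land where amplitude is largest.
stepped_epoch <- function(amplitudes, classes, maps, fs = 250) {
  stopifnot(length(amplitudes) == length(classes))
  x <- vapply(seq_along(classes),
              function(j) amplitudes[j] * maps[classes[j], ],
              numeric(ncol(maps)))
  eeg_epoch(x, fs)
}

expect_maps_match <- function(found, truth, min_r = 0.95) {
  r <- abs(cor(t(as.matrix(found)), t(as.matrix(truth))))
  expect_true(all(apply(r, 2, max) >= min_r),
              label = sprintf("all true maps recovered with |r| >= %.2f (min %.3f)",
                              min_r, min(apply(r, 2, max))))
}
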