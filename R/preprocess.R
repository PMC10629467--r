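#' Zero-phase band-pass filter
#'
#' Filters each channel with a 4th-order Butterworth band-pass applied
#' forward and backward (zero phase, squared magnitude response). The
#' analysis band for microstate work is 2-20 Hz.
#'
#' @param x An [eeg_recording()], [eeg_epoch()] or channels-x-samples matrix.
#' @param low,high Band edges in Hz; `high` must be below the Nyquist rate.
#' @param sampling_rate Required when `x` is a bare matrix.
#' @return Same type as `x`, filtered.
#' @export
#' @examples
#' fs <- 250
#' t <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
#' x <- rbind(sin(2 * pi * 10 * t), -sin(2 * pi * 10 * t))
#' y <- bandpass_filter(x, 2, 20, sampling_rate = fs)
bandpass_filter <- function(x, low = 2, high = 20, sampling_rate = NULL) {
  fs <- sampling_rate %||% x$sampling_rate
  if (is.null(fs)) stop("`sampling_rate` is required for matrix input", call. = FALSE)
  if (!(low > 0 && low < high)) stop("need 0 < low < high", call. = FALSE)
  if (high >= fs / 2) stop("`high` must be below the Nyquist frequency", call. = FALSE)
  mat <- epoch_matrix(x)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  # odd-reflection padding tames filtfilt edge transients (incl. DC offsets)
  n <- ncol(mat)
  pad <- min(n - 1L, as.integer(round(fs / low)))
  out <- t(apply(mat, 1L, function(ch) {
    padded <- c(2 * ch[1L] - rev(ch[2:(pad + 1L)]), ch,
                2 * ch[n] - rev(ch[(n - pad):(n - 1L)]))
    signal::filtfilt(bf, padded)[(pad + 1L):(pad + n)]
  }))
  dimnames(out) <- dimnames(mat)
  replace_data(x, out)
}

#' Re-reference to the average reference
#'
#' Subtracts, at every time sample, the mean potential across channels, so
#' each map sums to zero. Idempotent.
#'
#' @param x An [eeg_recording()], [eeg_epoch()] or channels-x-samples matrix.
#' @return Same type as `x`, average-referenced.
#' @export
#' @examples
#' average_reference(matrix(c(1, 2, 3), ncol = 1))
average_reference <- function(x) {
  mat <- epoch_matrix(x)
  if (nrow(mat) < 2L) stop("average reference needs at least 2 channels", call. = FALSE)
  out <- sweep(mat, 2L, colMeans(mat))
  replace_data(x, out)
}

replace_data <- function(x, mat) {
  if (inherits(x, c("eeg_recording", "eeg_epoch"))) {
    x$data <- mat
    x
  } else {
    mat
  }
}

#' Detect suppression EEG
#'
#' Suppression EEG is defined as a period of low voltage with an amplitude
#' below `threshold` microvolts. Amplitude is measured as the peak-to-peak
#' excursion per channel over the epoch, maximised over channels, on the
#' filtered signal.
#'
#' @param epoch An [eeg_epoch()] or channels-x-samples matrix, microvolts.
#' @param threshold Amplitude threshold in microvolts (default 10).
#' @return `TRUE` iff the maximal peak-to-peak amplitude is below `threshold`.
#' @export
#' @examples
#' detect_suppression(matrix(c(-2.5, 2.5, 2.5, -2.5), nrow = 2))  # 5 uV -> TRUE
detect_suppression <- function(epoch, threshold = 10) {
  mat <- epoch_matrix(epoch)
  if (length(mat) == 0L) stop("empty epoch", call. = FALSE)
  ptp <- apply(mat, 1L, function(ch) diff(range(ch)))
  max(ptp) < threshold
}

#' Group epochs into EEG intervals
#'
#' Assembles a time-ordered list of epochs into epoch sets ("intervals") of
#' at most `epochs_per_set` epochs, greedily in time order and separately by
#' suppression status. An open set is closed when it is full or when the next
#' candidate epoch starts more than `max_span` minutes after the set's first
#' epoch (the study sampled non-suppression intervals about every 30 min).
#' Sets with fewer than `min_epochs` members are dropped.
#'
#' @param epochs List of [eeg_epoch()] objects with onsets and suppression
#'   flags.
#' @param epochs_per_set Maximum epochs per set (default 24; 24 x 2.5 s = 1
#'   minute of EEG).
#' @param max_span Maximal distance in minutes between a set's first epoch
#'   and any member (default 15).
#' @param min_epochs Minimal set size (default 2).
#' @param patient_id Identifier stored on the emitted sets.
#' @return List of [epoch_set()] objects ordered by mean time.
#' @export
assemble_intervals <- function(epochs, epochs_per_set = 24L, max_span = 15,
                               min_epochs = 2L, patient_id = NA_character_) {
  if (length(epochs) == 0L) return(list())
  onsets <- vapply(epochs, function(e) e$onset, numeric(1))
  epochs <- epochs[order(onsets)]
  open <- list(`TRUE` = NULL, `FALSE` = NULL)   # one open set per status
  closed <- list()
  close_set <- function(members) {
    if (length(members) >= min_epochs) {
      closed[[length(closed) + 1L]] <<- epoch_set(members, patient_id)
    }
  }
  for (e in epochs) {
    key <- as.character(e$suppression)
    cur <- open[[key]]
    if (!is.null(cur) &&
        (length(cur) >= epochs_per_set ||
         e$onset - cur[[1L]]$onset > max_span)) {
      close_set(cur)
      cur <- NULL
    }
    open[[key]] <- c(cur, list(e))
  }
  for (key in names(open)) close_set(open[[key]])
  if (length(closed) == 0L) return(list())
  closed[order(vapply(closed, function(s) s$mean_time, numeric(1)))]
}

#' Resample a recording or epoch
#'
#' Polyphase resampling of each channel to a new integer sampling rate.
#' Acquisition systems often sample in the kHz range; microstate analysis is
#' conventionally run near 250 Hz (about 4 ms temporal resolution).
#'
#' @param x An [eeg_recording()], [eeg_epoch()] or matrix.
#' @param rate Target sampling rate in Hz (integer).
#' @param sampling_rate Required for matrix input.
#' @return Same type as `x` at the new rate.
#' @export
resample_signal <- function(x, rate, sampling_rate = NULL) {
  fs <- sampling_rate %||% x$sampling_rate
  if (is.null(fs)) stop("`sampling_rate` is required for matrix input", call. = FALSE)
  if (fs != as.integer(fs) || rate != as.integer(rate)) {
    stop("resampling requires integer sampling rates", call. = FALSE)
  }
  if (rate == fs) return(x)
  g <- gcd(as.integer(rate), as.integer(fs))
  p <- as.integer(rate) %/% g
  q <- as.integer(fs) %/% g
  mat <- epoch_matrix(x)
  out <- t(apply(mat, 1L, function(ch) signal::resample(ch, p, q)))
  x <- replace_data(x, out)
  if (inherits(x, c("eeg_recording", "eeg_epoch"))) {
    x$sampling_rate <- rate
    if (inherits(x, "eeg_epoch")) x$duration <- ncol(out) / rate
  }
  x
}

gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)
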