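#' Canonical 10/20 channel order
#'
#' The 19 scalp electrode labels of the International 10/20 system in the
#' fixed order used throughout the package. Multichannel inputs with channel
#' labels are reordered to this sequence.
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' channels_1020()
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Continuous multichannel EEG recording
#'
#' Container for a continuous channels-by-samples potential matrix in
#' microvolts with its montage and sampling rate.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names; when 19
#'   channels carry 10/20 labels the rows are reordered to [channels_1020()].
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("a recording needs at least 2 channels", call. = FALSE)
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number", call. = FALSE)
  }
  if (!is.null(channel_labels)) {
    if (length(channel_labels) != nrow(data)) {
      stop("`channel_labels` length must match the channel count", call. = FALSE)
    }
    if (setequal(channel_labels, channels_1020())) {
      ord <- match(channels_1020(), channel_labels)
      data <- data[ord, , drop = FALSE]
      channel_labels <- channels_1020()
    }
    rownames(data) <- channel_labels
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels, n_channels = nrow(data)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Analysed EEG epoch
#'
#' A short (nominally 2.5 s) filtered, average-referenced segment of
#' multichannel EEG, tagged with its onset time relative to anaesthesia
#' induction and its suppression status. Suppression epochs (peak-to-peak
#' amplitude below 10 microvolts) may be shorter than the nominal length.
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param onset Onset time in minutes since anaesthesia induction.
#' @param suppression Logical suppression flag.
#' @param channel_labels Optional channel names.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, sampling_rate, onset = 0,
                      suppression = FALSE, channel_labels = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("an epoch needs at least 2 channels", call. = FALSE)
  if (ncol(data) < 1L) stop("an epoch needs at least 1 sample", call. = FALSE)
  if (!is_flag(suppression)) stop("`suppression` must be TRUE or FALSE", call. = FALSE)
  if (!is.null(channel_labels)) rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = sampling_rate, onset = onset,
         suppression = suppression,
         duration = ncol(data) / sampling_rate,
         channel_labels = channel_labels),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d ch x %d samples @ %g Hz, onset %.1f min, %s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, x$onset,
              if (x$suppression) "suppression" else "non-suppression"))
  invisible(x)
}

#' Epoch set (EEG interval)
#'
#' A group of up to `epochs_per_set` epochs of identical suppression status,
#' summarising roughly one minute of EEG around one time point of the
#' anaesthesia course. Its `mean_time` is the arithmetic mean of the member
#' epochs' onsets and is the "anaesthesia duration" covariate of the trend
#' models.
#'
#' @param epochs List of [eeg_epoch()] objects sharing a suppression status.
#' @param patient_id Patient identifier.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, patient_id = NA_character_) {
  if (length(epochs) < 2L) {
    stop("an epoch set needs at least 2 epochs", call. = FALSE)
  }
  supp <- vapply(epochs, function(e) e$suppression, logical(1))
  if (length(unique(supp)) != 1L) {
    stop("all epochs of a set must share suppression status", call. = FALSE)
  }
  onsets <- vapply(epochs, function(e) e$onset, numeric(1))
  structure(
    list(epochs = epochs, patient_id = patient_id,
         mean_time = mean(onsets), suppression = supp[1L],
         n_epochs = length(epochs)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> patient %s: %d %s epochs, mean time %.1f min\n",
              x$patient_id, x$n_epochs,
              if (x$suppression) "suppression" else "non-suppression",
              x$mean_time))
  invisible(x)
}

# Extract the data matrix from an epoch / recording / plain matrix.
epoch_matrix <- function(x) {
  if (inherits(x, c("eeg_epoch", "eeg_recording"))) x$data else as.matrix(x)
}
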