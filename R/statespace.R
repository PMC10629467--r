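#' Spatial principal component analysis of an epoch
#'
#' Eigen-decomposition of the channel second-moment (covariance over time)
#' matrix of an average-referenced epoch. Returns exactly as many
#' eigenvalue/eigenvector pairs as channels; the average reference confines
#' the data to a (k-1)-dimensional subspace, so the smallest eigenvalue is
#' numerically zero.
#'
#' @param epoch An [eeg_epoch()] or channels-x-samples matrix,
#'   average-referenced, in microvolts.
#' @return An object of class `spatial_spectrum`: list with `eigenvalues`
#'   (descending, in squared microvolts, negatives clamped to 0) and
#'   `eigenvectors` (columns, orthonormal).
#' @export
spatial_pca <- function(epoch) {
  mat <- epoch_matrix(epoch)
  if (all(mat == 0)) {
    stop(structure(class = c("eegstates_degenerate", "error", "condition"),
                   list(message = "all-zero epoch: degenerate spatial spectrum",
                        call = NULL)))
  }
  cov_ch <- tcrossprod(mat) / ncol(mat)
  e <- eigen(cov_ch, symmetric = TRUE)
  structure(list(eigenvalues = pmax(e$values, 0), eigenvectors = e$vectors),
            class = "spatial_spectrum")
}

#' @export
print.spatial_spectrum <- function(x, ...) {
  cat(sprintf("<spatial_spectrum> %d eigenvalues, sigma = %.4g uV^2, omega = %.3f\n",
              length(x$eigenvalues), descriptor_sigma(x), descriptor_omega(x)))
  invisible(x)
}

#' Sigma: total EEG variance
#'
#' The sum of all spatial-PCA eigenvalues, i.e. the overall variance of the
#' multichannel EEG across channels and time points (equals the trace of the
#' channel covariance). Quadratic in amplitude scale, invariant to channel
#' rotations.
#'
#' @param spectrum A [spatial_pca()] result (or an epoch, decomposed first).
#' @return Sigma in squared microvolts.
#' @export
descriptor_sigma <- function(spectrum) {
  if (!inherits(spectrum, "spatial_spectrum")) spectrum <- spatial_pca(spectrum)
  sum(spectrum$eigenvalues)
}

#' Phi: generalized frequency
#'
#' The power-normalized speed of the state space trajectory:
#' `phi = (1 / 2*pi) * sqrt(sum ||u(t+1) - u(t)||^2 * fs^2 / sum ||u(t)||^2)`
#' where `u(t)` is the multichannel sample at time `t` (projections onto the
#' PCA eigenvectors preserve norms, so the raw channel trajectory is used).
#' For a multichannel pure sinusoid at `f` Hz this returns `f` up to forward-
#' difference discretization error. Invariant to amplitude scale and channel
#' rotations.
#'
#' @param epoch An [eeg_epoch()] or channels-x-samples matrix (>= 2 samples).
#' @param sampling_rate Required when `epoch` is a bare matrix.
#' @return Phi in Hz.
#' @export
descriptor_phi <- function(epoch, sampling_rate = NULL) {
  fs <- sampling_rate %||% epoch$sampling_rate
  if (is.null(fs)) stop("`sampling_rate` is required for matrix input", call. = FALSE)
  mat <- epoch_matrix(epoch)
  n <- ncol(mat)
  if (n < 2L) stop("phi needs at least 2 samples", call. = FALSE)
  power <- sum(mat^2)
  if (power == 0) {
    stop(structure(class = c("eegstates_degenerate", "error", "condition"),
                   list(message = "zero-power epoch: phi undefined", call = NULL)))
  }
  d <- (mat[, -1L, drop = FALSE] - mat[, -n, drop = FALSE]) * fs
  sqrt(sum(d^2) / power) / (2 * pi)
}

#' Omega: spatial complexity
#'
#' The antilog of the Shannon entropy of the normalized eigenvalue spectrum:
#' with `p_i = lambda_i / sum(lambda)`, `omega = exp(-sum p_i log p_i)`
#' (`0 log 0 = 0`). A lower-bound estimate of the number of uncorrelated
#' generator processes, ranging from 1 (rank-1 data) to `k` (equal
#' eigenvalues on `k` channels). Eigenvalues below `1e-12 * max(lambda)` are
#' clamped to zero before the entropy. Invariant to amplitude scale and
#' channel rotations.
#'
#' @param spectrum A [spatial_pca()] result (or an epoch, decomposed first).
#' @return Omega, dimensionless in `[1, k]`.
#' @export
descriptor_omega <- function(spectrum) {
  if (!inherits(spectrum, "spatial_spectrum")) spectrum <- spatial_pca(spectrum)
  lam <- spectrum$eigenvalues
  lam[lam < 1e-12 * max(lam)] <- 0
  if (sum(lam) == 0) {
    stop(structure(class = c("eegstates_degenerate", "error", "condition"),
                   list(message = "all-zero spectrum: omega undefined", call = NULL)))
  }
  p <- lam / sum(lam)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' State space descriptors of one epoch
#'
#' Computes sigma, phi and omega for one epoch.
#'
#' @param epoch An [eeg_epoch()] or matrix.
#' @param sampling_rate Required for matrix input.
#' @return Named numeric vector `c(sigma, phi, omega)`.
#' @export
state_space_descriptors <- function(epoch, sampling_rate = NULL) {
  sp <- spatial_pca(epoch)
  c(sigma = descriptor_sigma(sp),
    phi = descriptor_phi(epoch, sampling_rate),
    omega = descriptor_omega(sp))
}

#' Average descriptors over an epoch set
#'
#' Arithmetic mean of the per-epoch sigma, phi and omega over all epochs of a
#' set, yielding one state space record per interval.
#'
#' @param set An [epoch_set()], or a list of per-epoch descriptor vectors
#'   from [state_space_descriptors()].
#' @return One-row `data.frame`: `patient_id`, `mean_time`, `suppression`,
#'   `sigma`, `phi`, `omega`, `n_epochs` (identifiers `NA` for bare lists).
#' @export
average_descriptors <- function(set) {
  if (inherits(set, "epoch_set")) {
    recs <- lapply(set$epochs, state_space_descriptors)
    ids <- data.frame(patient_id = set$patient_id, mean_time = set$mean_time,
                      suppression = set$suppression)
  } else {
    recs <- set
    ids <- data.frame(patient_id = NA_character_, mean_time = NA_real_,
                      suppression = NA)
  }
  if (length(recs) == 0L) {
    stop(structure(class = c("eegstates_missing", "error", "condition"),
                   list(message = "empty epoch set: no descriptor record",
                        call = NULL)))
  }
  m <- do.call(rbind, recs)
  cbind(ids, as.data.frame(t(colMeans(m))), n_epochs = length(recs))
}

#' Descriptor table for assembled intervals
#'
#' @param sets List of [epoch_set()]s.
#' @return `data.frame`, one row per interval, from [average_descriptors()].
#' @export
descriptor_table <- function(sets) {
  do.call(rbind, lapply(sets, average_descriptors))
}
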