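#' Back-fit microstate class maps to an epoch
#'
#' Labels every sample of an epoch with a microstate class: each GFP-peak
#' sample gets the class whose map has maximal absolute spatial correlation
#' with the momentary map (ties break to the lower class index), and every
#' other sample inherits the label of the temporally nearest peak (exact
#' distance ties go to the earlier peak). Correlation-based, hence invariant
#' to amplitude scaling of the epoch.
#'
#' @param epoch An [eeg_epoch()] or channels-x-samples matrix,
#'   average-referenced.
#' @param solution A [microstate_solution()] (grand-mean class maps).
#' @return Integer vector of per-sample class indices (1-based, indexing
#'   `solution$labels`).
#' @export
backfit <- function(epoch, solution) {
  mat <- epoch_matrix(epoch)
  cm <- solution$class_maps
  if (nrow(mat) != ncol(cm)) stop("channel counts differ", call. = FALSE)
  peaks <- find_gfp_peaks(mat)
  if (length(peaks) == 0L) {
    stop(structure(class = c("eegstates_unlabelled", "error", "condition"),
                   list(message = "epoch has no GFP peaks; cannot back-fit",
                        call = NULL)))
  }
  # polarity-blind correlation of peak maps with class maps
  pk_maps <- mat[, peaks, drop = FALSE]
  pk_maps <- sweep(pk_maps, 2L, colMeans(pk_maps))
  cmz <- cm - rowMeans(cm)
  num <- abs(t(pk_maps) %*% t(cmz))
  den <- outer(sqrt(colSums(pk_maps^2)), sqrt(rowSums(cmz^2)))
  r <- num / den
  r[!is.finite(r)] <- -Inf
  peak_labels <- max.col(r, ties.method = "first")
  # nearest-neighbour interpolation by sample index; earlier peak wins ties
  n <- ncol(mat)
  nearest <- vapply(seq_len(n), function(i) which.min(abs(peaks - i)), integer(1))
  peak_labels[nearest]
}

#' Segmentation of an epoch into microstates
#'
#' Run-length encodes per-sample class labels into contiguous microstate
#' segments, computes each segment's mean GFP, and flags segments touching
#' the first or last sample as truncated (their true extent is unobserved, so
#' they are excluded from quantifier statistics).
#'
#' @param labels Integer per-sample class labels (from [backfit()]).
#' @param epoch The labelled [eeg_epoch()] or matrix (for GFP and rate).
#' @param sampling_rate Required when `epoch` is a bare matrix.
#' @return An object of class `segmentation`: list with `labels`, a
#'   `segments` data.frame (`class`, `start`, `end`, `length`, `mean_gfp`,
#'   `truncated`) and `sampling_rate`/`duration`.
#' @export
segment_and_filter <- function(labels, epoch, sampling_rate = NULL) {
  mat <- epoch_matrix(epoch)
  fs <- sampling_rate %||% epoch$sampling_rate
  if (is.null(fs)) stop("`sampling_rate` is required for matrix input", call. = FALSE)
  if (length(labels) != ncol(mat)) stop("labels must cover the epoch", call. = FALSE)
  g <- gfp_series(mat)
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- data.frame(
    class = r$values, start = starts, end = ends, length = r$lengths,
    mean_gfp = vapply(seq_along(starts),
                      function(i) mean(g[starts[i]:ends[i]]), numeric(1)),
    truncated = starts == 1L | ends == length(labels)
  )
  structure(list(labels = as.integer(labels), segments = segs,
                 sampling_rate = fs, duration = ncol(mat) / fs),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d samples, %d segments (%d retained)\n",
              length(x$labels), nrow(x$segments), sum(!x$segments$truncated)))
  invisible(x)
}

#' Microstate quantifiers for a set of epochs
#'
#' Aggregates the retained (non-truncated) segments of all epochs in a set
#' into the three per-class microstate quantifiers:
#' * `duration_ms`: mean retained-segment length x 1000 / sampling rate;
#' * `occurrence_per_s`: retained segment count / total analysed seconds
#'   (the denominator is the full epoch time of the set);
#' * `gfp_uv`: mean over retained segments of the segment mean GFP.
#'
#' A class with no retained segment in the set gets `NA` duration and GFP
#' (unobserved, not zero) and occurrence 0.
#'
#' @param segmentations List of [segment_and_filter()] results, one per epoch
#'   of the set.
#' @param n_classes Number of classes (defaults to the largest label seen).
#' @param labels Optional class label names.
#' @return `data.frame` with one row per class: `class`, `duration_ms`,
#'   `occurrence_per_s`, `gfp_uv`, `n_segments`.
#' @export
compute_quantifiers <- function(segmentations, n_classes = NULL, labels = NULL) {
  if (inherits(segmentations, "segmentation")) segmentations <- list(segmentations)
  stopifnot(length(segmentations) >= 1L)
  segs <- do.call(rbind, lapply(segmentations, function(s) {
    s$segments[!s$segments$truncated, , drop = FALSE]
  }))
  fs <- segmentations[[1L]]$sampling_rate
  total_s <- sum(vapply(segmentations, function(s) s$duration, numeric(1)))
  n_classes <- n_classes %||%
    max(unlist(lapply(segmentations, function(s) s$labels)), 1L)
  labels <- labels %||% microstate_labels(n_classes)
  out <- data.frame(class = labels,
                    duration_ms = NA_real_, occurrence_per_s = 0,
                    gfp_uv = NA_real_, n_segments = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_classes)) {
    sk <- segs[segs$class == k, , drop = FALSE]
    out$n_segments[k] <- nrow(sk)
    out$occurrence_per_s[k] <- nrow(sk) / total_s
    if (nrow(sk) > 0L) {
      out$duration_ms[k] <- mean(sk$length) * 1000 / fs
      out$gfp_uv[k] <- mean(sk$mean_gfp)
    }
  }
  out
}

#' Quantifier table for assembled intervals
#'
#' Back-fits a grand-mean microstate solution to every epoch of every epoch
#' set and returns the long-format quantifier table (one row per interval and
#' class) that the trend models consume. Epochs without GFP peaks are
#' skipped.
#'
#' @param sets List of [epoch_set()]s.
#' @param solution Grand-mean [microstate_solution()].
#' @return `data.frame`: `patient_id`, `mean_time`, `suppression`, `class`,
#'   `duration_ms`, `occurrence_per_s`, `gfp_uv`, `n_segments`.
#' @export
quantifier_table <- function(sets, solution) {
  rows <- lapply(sets, function(s) {
    segm <- list()
    for (ep in s$epochs) {
      lab <- tryCatch(backfit(ep, solution),
                      eegstates_unlabelled = function(e) NULL)
      if (is.null(lab)) next
      segm[[length(segm) + 1L]] <- segment_and_filter(lab, ep)
    }
    if (length(segm) == 0L) return(NULL)
    q <- compute_quantifiers(segm, n_classes = nrow(solution$class_maps),
                             labels = solution$labels)
    cbind(data.frame(patient_id = s$patient_id, mean_time = s$mean_time,
                     suppression = s$suppression), q)
  })
  do.call(rbind, rows)
}
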