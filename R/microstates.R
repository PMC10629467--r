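#' Global field power of a scalp map
#'
#' GFP is the spatial standard deviation of an average-referenced potential
#' map at one time point: `sqrt(mean((v - mean(v))^2))`. It indexes the
#' momentary strength of synchronous whole-brain activity.
#'
#' @param map Numeric vector of per-channel potentials (microvolts).
#' @return GFP in microvolts (non-negative; 0 only for a flat map).
#' @export
#' @examples
#' gfp(c(1, -1))  # 1
gfp <- function(map) {
  map <- as.numeric(map)
  sqrt(mean((map - mean(map))^2))
}

#' GFP time series of an epoch
#'
#' @param epoch An [eeg_epoch()] or channels-x-samples matrix.
#' @return Numeric vector of per-sample GFP values.
#' @export
gfp_series <- function(epoch) {
  mat <- epoch_matrix(epoch)
  mat <- sweep(mat, 2L, colMeans(mat))
  sqrt(colMeans(mat^2))
}

#' Find GFP peaks
#'
#' Returns the sample indices of strict local maxima of the epoch's GFP time
#' series. Maps at GFP peaks have maximal topographic signal-to-noise and are
#' the input to microstate clustering. The first and last samples are never
#' peaks; a constant series yields no peaks.
#'
#' @param epoch An [eeg_epoch()] or channels-x-samples matrix (>= 3 samples).
#' @return Integer vector of 1-based sample indices (possibly empty).
#' @export
find_gfp_peaks <- function(epoch) {
  g <- gfp_series(epoch)
  n <- length(g)
  if (n < 3L) stop("need at least 3 samples to find peaks", call. = FALSE)
  i <- 2:(n - 1L)
  i[g[i] > g[i - 1L] & g[i] > g[i + 1L]]
}

#' Spatial correlation between two scalp maps
#'
#' Pearson correlation of the two maps across channels; with
#' `ignore_polarity` the absolute value is returned, matching the
#' polarity-invariant treatment of microstate maps.
#'
#' @param map1,map2 Numeric per-channel vectors of equal length.
#' @param ignore_polarity Return `|r|` instead of `r` (default `FALSE`).
#' @return Correlation in `[-1, 1]` (or `[0, 1]`).
#' @export
spatial_correlation <- function(map1, map2, ignore_polarity = FALSE) {
  map1 <- as.numeric(map1); map2 <- as.numeric(map2)
  if (length(map1) != length(map2)) stop("channel counts differ", call. = FALSE)
  if (sd(map1) == 0 || sd(map2) == 0) {
    stop("spatial correlation undefined for a zero-variance map", call. = FALSE)
  }
  r <- cor(map1, map2)
  if (ignore_polarity) abs(r) else r
}

#' Microstate class map solution
#'
#' @param class_maps Numeric matrix, classes x channels; rows unit-norm and
#'   average-referenced.
#' @param labels Class labels (defaults to A, B, C, ...).
#' @param explained_variance Fraction of map variance explained, in `[0, 1]`.
#' @param template_correlations Optional per-class `|r|` to normative maps.
#' @param degenerate Logical per-class flag for classes that attracted no maps.
#' @return An object of class `microstate_solution`.
#' @export
microstate_solution <- function(class_maps, labels = NULL,
                                explained_variance = NA_real_,
                                template_correlations = NULL,
                                degenerate = NULL) {
  class_maps <- as.matrix(class_maps)
  k <- nrow(class_maps)
  labels <- labels %||% microstate_labels(k)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (!is.na(explained_variance) &&
      (explained_variance < -1e-12 || explained_variance > 1 + 1e-12)) {
    stop("explained_variance must lie in [0, 1]", call. = FALSE)
  }
  rownames(class_maps) <- labels
  structure(
    list(class_maps = class_maps, labels = labels,
         explained_variance = explained_variance,
         template_correlations = template_correlations,
         degenerate = degenerate %||% rep(FALSE, k)),
    class = "microstate_solution"
  )
}

#' @export
print.microstate_solution <- function(x, ...) {
  cat(sprintf("<microstate_solution> %d classes (%s), %d channels",
              nrow(x$class_maps), paste(x$labels, collapse = ""),
              ncol(x$class_maps)))
  if (!is.na(x$explained_variance)) {
    cat(sprintf(", explained variance %.3f", x$explained_variance))
  }
  if (any(x$degenerate)) {
    cat(sprintf(" [degenerate: %s]", paste(x$labels[x$degenerate], collapse = ",")))
  }
  cat("\n")
  invisible(x)
}

# Coerce list-of-vectors / solution / matrix into a maps x channels matrix.
as_map_matrix <- function(maps) {
  if (inherits(maps, "microstate_solution")) return(maps$class_maps)
  if (is.list(maps)) return(do.call(rbind, lapply(maps, as.numeric)))
  as.matrix(maps)
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# Deterministic sign convention: largest-|value| component positive.
canonical_sign <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) s <- 1
  v * s
}

#' Polarity-invariant modified k-means microstate clustering
#'
#' Clusters average-referenced scalp maps (typically GFP-peak maps) into
#' `n_classes` microstate class maps, ignoring map polarity: a map and its
#' sign-flipped copy are equivalent. Maps are GFP-normalized before
#' clustering so high-amplitude epochs do not dominate. Each iteration
#' assigns every map to the class whose map it correlates with most strongly
#' in absolute value, then recomputes each class map as the first principal
#' eigenvector of the outer-product sum of its assigned maps. The best of
#' `restarts` seeded random restarts (by explained variance) is returned.
#'
#' @param maps Matrix (maps x channels), list of map vectors, or an
#'   [eeg_epoch()] whose GFP-peak maps are used.
#' @param n_classes Number of microstate classes (default 4).
#' @param restarts Random restarts (default 20).
#' @param max_iter Iteration cap per restart (default 200).
#' @param tol Convergence tolerance on the explained-variance gain.
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return A [microstate_solution()].
#' @export
modified_kmeans <- function(maps, n_classes = 4L, restarts = 20L,
                            max_iter = 200L, tol = 1e-6, seed = NULL) {
  if (inherits(maps, "eeg_epoch")) {
    pk <- find_gfp_peaks(maps)
    maps <- t(maps$data[, pk, drop = FALSE])
  }
  x <- as_map_matrix(maps)
  keep <- sqrt(rowSums(x^2)) > 0
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  if (n < n_classes) stop("fewer maps than classes", call. = FALSE)
  xn <- unit_rows(x)

  run_once <- function() {
    cm <- xn[sample.int(n, n_classes), , drop = FALSE]
    ev_prev <- -Inf
    assign_prev <- NULL
    for (iter in seq_len(max_iter)) {
      proj <- xn %*% t(cm)                    # n x K signed correlations
      assign <- max.col(proj^2, ties.method = "first")
      ev <- mean(proj[cbind(seq_len(n), assign)]^2)
      for (k in seq_len(n_classes)) {
        idx <- which(assign == k)
        if (length(idx) == 0L) next
        m <- crossprod(xn[idx, , drop = FALSE])
        cm[k, ] <- canonical_sign(eigen(m, symmetric = TRUE)$vectors[, 1L])
      }
      if (!is.null(assign_prev) && identical(assign, assign_prev)) break
      if (ev - ev_prev < tol && iter > 1L) break
      ev_prev <- ev
      assign_prev <- assign
    }
    proj <- xn %*% t(cm)
    assign <- max.col(proj^2, ties.method = "first")
    list(cm = cm, ev = mean(proj[cbind(seq_len(n), assign)]^2), assign = assign)
  }

  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      cand <- run_once()
      if (is.null(best) || cand$ev > best$ev) best <- cand
    }
    best
  })
  degenerate <- tabulate(best$assign, nbins = n_classes) == 0L
  cm <- t(apply(best$cm, 1L, canonical_sign))
  microstate_solution(cm, explained_variance = best$ev, degenerate = degenerate)
}

#' Variance explained by a microstate solution
#'
#' Fraction of the total squared map norm captured when every input map is
#' projected, polarity-blind, onto its best-fitting class map.
#'
#' @param solution A [microstate_solution()] (unit-norm class maps).
#' @param maps Matrix (maps x channels) or list of maps.
#' @return Fraction in `[0, 1]`.
#' @export
explained_variance <- function(solution, maps) {
  cm <- unit_rows(as_map_matrix(solution))
  x <- as_map_matrix(maps)
  if (ncol(cm) != ncol(x)) stop("channel counts differ", call. = FALSE)
  total <- sum(x^2)
  if (total == 0) return(1)
  proj <- x %*% t(cm)
  best <- apply(proj^2, 1L, max)
  ev <- sum(best) / total
  min(max(ev, 0), 1)
}

# Best permutation + signs aligning `maps` (K x ch) to `ref` (K x ch);
# maximizes the summed squared correlation within class.
best_alignment <- function(ref, maps) {
  k <- nrow(ref)
  refn <- unit_rows(ref)
  mapn <- unit_rows(maps)
  r <- refn %*% t(mapn)                       # r[i, j]: ref class i vs map j
  perms <- permutations(k)
  best_score <- -Inf
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    perm <- perms[p, ]
    score <- sum(r[cbind(seq_len(k), perm)]^2)
    if (score > best_score + 1e-12) {
      best_score <- score
      best <- perm
    }
  }
  signs <- sign(r[cbind(seq_len(k), best)])
  signs[signs == 0] <- 1
  list(perm = best, signs = signs, score = best_score)
}

#' Align and average microstate solutions
#'
#' Averages several microstate solutions into one, first choosing per
#' solution the class-label permutation and polarity signs that maximize the
#' topographic variance shared within class (exhaustive search over
#' permutations — exact for four classes). Used hierarchically: per-interval
#' solutions are averaged into time-conditional group means, and those into
#' grand means. Intervals contributing fewer than `min_datasets` solutions
#' are excluded.
#'
#' @param solutions List of [microstate_solution()]s (or class-map matrices)
#'   sharing channel count and class count.
#' @param min_datasets Minimal number of solutions (default 2); fewer raises
#'   an exclusion error of class `eegstates_exclusion`.
#' @return A [microstate_solution()] with unit-norm averaged maps.
#' @export
align_and_average <- function(solutions, min_datasets = 2L) {
  if (length(solutions) < min_datasets) {
    stop(structure(
      class = c("eegstates_exclusion", "error", "condition"),
      list(message = sprintf("only %d solution(s); interval excluded (< %d data sets)",
                             length(solutions), min_datasets),
           call = NULL)))
  }
  mats <- lapply(solutions, function(s) unit_rows(as_map_matrix(s)))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("solutions must share class and channel counts", call. = FALSE)
  }
  ref <- mats[[1L]]
  for (pass in 1:2) {
    acc <- matrix(0, nrow(ref), ncol(ref))
    for (m in mats) {
      al <- best_alignment(ref, m)
      acc <- acc + al$signs * m[al$perm, , drop = FALSE]
    }
    ref <- unit_rows(acc / length(mats))
  }
  ref <- t(apply(ref, 1L, canonical_sign))
  labels <- if (inherits(solutions[[1L]], "microstate_solution")) {
    solutions[[1L]]$labels
  } else NULL
  microstate_solution(ref, labels = labels)
}

#' Label microstate classes against normative templates
#'
#' Finds the one-to-one assignment of solution maps to template maps that
#' maximizes the summed absolute spatial correlation, by exhaustive search
#' over all permutations (24 for four classes). Ties break to the
#' lexicographically first label order.
#'
#' @param solution A [microstate_solution()].
#' @param templates Template maps: matrix (classes x channels) with label
#'   rownames, or a [microstate_solution()]; defaults to
#'   [normative_templates()] when channel counts match.
#' @return The solution with reordered rows, labels, and per-class `|r|`
#'   stored in `template_correlations`.
#' @export
label_by_template <- function(solution, templates = normative_templates()) {
  tm <- as_map_matrix(templates)
  tl <- rownames(tm) %||% microstate_labels(nrow(tm))
  sm <- solution$class_maps
  if (ncol(tm) != ncol(sm)) stop("template channel count differs", call. = FALSE)
  if (nrow(tm) != nrow(sm)) stop("template class count differs", call. = FALSE)
  k <- nrow(tm)
  r <- abs(cor(t(tm), t(sm)))                 # r[i, j]: template i vs class j
  perms <- permutations(k)
  best_score <- -Inf
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    perm <- perms[p, ]                        # template i <- solution map perm[i]
    score <- sum(r[cbind(seq_len(k), perm)])
    if (score > best_score + 1e-12) {
      best_score <- score
      best <- perm
    }
  }
  cors <- r[cbind(seq_len(k), best)]
  microstate_solution(sm[best, , drop = FALSE], labels = tl,
                      explained_variance = solution$explained_variance,
                      template_correlations = setNames(cors, tl),
                      degenerate = solution$degenerate[best])
}

#' Synthetic normative microstate templates (10/20, 19 channels)
#'
#' Loads the packaged synthetic approximation of the four canonical
#' microstate class topographies A-D on the 19-channel 10/20 montage,
#' constructed from idealized electrode geometry (A/B: opposite
#' occipito-frontal diagonals; C: posterior-anterior midline gradient; D:
#' fronto-central focus). These are *not* published normative maps; they
#' reproduce the canonical maps' qualitative geometry for labelling and
#' simulation. Users with montage-matched normative maps should pass those to
#' [label_by_template()] instead.
#'
#' @return Matrix 4 x 19 (rows A-D, columns [channels_1020()]), rows
#'   average-referenced and unit-norm.
#' @export
normative_templates <- function() {
  path <- system.file("extdata", "templates_1020_synthetic.csv",
                      package = "eegstates", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
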