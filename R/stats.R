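standard_covariates <- function() {
  c("age", "sex", "mmse_band", "asa_band", "surgical_site", "anaesthetic",
    "randomization")
}

#' Fit the anaesthesia-duration trend model
#'
#' Covariate-adjusted linear mixed-effects model of one microstate quantifier
#' or state space descriptor over anaesthesia duration. The fixed part is the
#' three-way interaction `mean_time x suppression x pod` — expanded to the
#' four-way interaction with microstate `class` for quantifier responses —
#' plus additive covariates; the random part is an intercept per patient
#' (optionally a random duration slope). Reference levels are no POD, no
#' suppression, duration 0, class A. Fitted by REML via [lmerTest::lmer()];
#' term significance uses F-tests with Satterthwaite degrees of freedom (see
#' [anova_table()]).
#'
#' @param data Long-format `data.frame` with columns `patient_id`,
#'   `mean_time` (minutes), `suppression`, `pod` (logical or yes/no), the
#'   response, a `class` column for quantifier models, and the covariates.
#' @param response Response column name (one of duration_ms,
#'   occurrence_per_s, gfp_uv, sigma, phi, omega — any numeric column works).
#' @param kind `"descriptor"` (3-way) or `"quantifier"` (4-way, needs
#'   `class`).
#' @param covariates Adjustment covariates; defaults to those of the standard
#'   set present in `data` (age, sex, MMSE band, ASA band, surgical site,
#'   anaesthetic type, randomization arm).
#' @param random_slope Add a per-patient random duration slope (default
#'   `FALSE`, random intercept only).
#' @return An object of class `trend_model` wrapping the `lmerTest` fit, with
#'   a coefficient table (95% CIs, Satterthwaite p-values) in `$coefficients`.
#' @export
fit_trend_model <- function(data, response, kind = c("descriptor", "quantifier"),
                            covariates = NULL, random_slope = FALSE) {
  kind <- match.arg(kind)
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("response column not found", call. = FALSE)
  covariates <- covariates %||% intersect(standard_covariates(), names(data))
  needed <- c("patient_id", "mean_time", "suppression", "pod", covariates,
              if (kind == "quantifier") "class")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  data$suppression <- yes_no(data$suppression)
  data$pod <- yes_no(data$pod)
  if (kind == "quantifier") data$class <- factor(data$class)
  for (cv in covariates) {
    if (!is.numeric(data[[cv]])) data[[cv]] <- factor(data[[cv]])
  }
  pod_pat <- unique(data[, c("patient_id", "pod")])
  if (length(unique(pod_pat$pod)) < 2L || any(table(pod_pat$pod) < 2L)) {
    stop("need at least 2 patients per POD group for between-subject terms",
         call. = FALSE)
  }
  # A factor observed at a single level (e.g. no suppression interval survived
  # a threshold of 0) is dropped: the design degrades to the remaining cells.
  has_suppression <- length(unique(data$suppression)) >= 2L
  if (!has_suppression) {
    message("single suppression status observed: fitting the 2-cell ",
            "duration x POD design")
  }
  fixed_factors <- c(if (has_suppression) "suppression", "pod",
                     if (kind == "quantifier") "class")
  cells <- do.call(table, unname(data[fixed_factors]))
  if (any(cells == 0L)) {
    stop("empty design cell: the interaction is unidentifiable", call. = FALSE)
  }
  inter <- paste(c("mean_time", fixed_factors), collapse = " * ")
  ran <- if (random_slope) "(1 + mean_time | patient_id)" else "(1 | patient_id)"
  fml <- stats::reformulate(c(inter, covariates, ran), response = response)
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE,
                        control = lme4::lmerControl(optimizer = "bobyqa"))
  if (lme4::isSingular(fit)) {
    warning("singular random-effects fit: a variance component is estimated at ",
            "zero; fixed effects fall back on the residual variance", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"], df = sm[, "df"],
    lower = sm[, "Estimate"] - qt(0.975, sm[, "df"]) * sm[, "Std. Error"],
    upper = sm[, "Estimate"] + qt(0.975, sm[, "df"]) * sm[, "Std. Error"],
    p = sm[, "Pr(>|t|)"], row.names = NULL)
  structure(
    list(fit = fit, response = response, kind = kind, covariates = covariates,
         formula = fml, coefficients = coefs, data = data,
         has_suppression = has_suppression),
    class = "trend_model"
  )
}

yes_no <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "yes", "no")
  factor(as.character(x), levels = c("no", "yes"))
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("<trend_model> %s (%s): %s\n", x$response, x$kind,
              deparse(x$formula)))
  print(x$coefficients[, c("term", "estimate", "lower", "upper", "p")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' ANOVA-style term tests for a trend model
#'
#' @param model A [fit_trend_model()] result.
#' @param ddf Degrees-of-freedom method: `"Satterthwaite"` (default),
#'   `"Kenward-Roger"`, or `"lme4"` (no denominator df / p-values).
#' @param type Sum-of-squares type (default 3).
#' @return The `anova` table of the underlying fit.
#' @export
anova_table <- function(model, ddf = "Satterthwaite", type = 3) {
  stopifnot(inherits(model, "trend_model"))
  anova(model$fit, type = type, ddf = ddf)
}

# Reference-level / mean-covariate newdata row(s) for the model, with the
# requested cell and duration values.
cell_newdata <- function(model, durations, suppression, pod, class = NULL) {
  mf <- model$data
  nd <- data.frame(mean_time = durations)
  nd$suppression <- factor(if (suppression) "yes" else "no", levels = c("no", "yes"))
  nd$pod <- factor(if (pod) "yes" else "no", levels = c("no", "yes"))
  if (model$kind == "quantifier") {
    if (is.null(class)) stop("quantifier models need a `class`", call. = FALSE)
    lv <- levels(mf$class)
    if (!class %in% lv) stop("unknown class label", call. = FALSE)
    nd$class <- factor(class, levels = lv)
  }
  for (cv in model$covariates) {
    v <- mf[[cv]]
    nd[[cv]] <- if (is.numeric(v)) mean(v) else factor(levels(v)[1L], levels = levels(v))
  }
  nd
}

# Fixed-effects design rows for new data, restricted to the coefficients the
# fit retained (lme4 drops rank-deficient columns, as its own predict does).
fixed_model_matrix <- function(model, newdata) {
  tt <- delete.response(terms(model$fit, fixed.only = TRUE))
  x <- model.matrix(tt, newdata)
  x[, names(lme4::fixef(model$fit)), drop = FALSE]
}

#' Slope of anaesthesia duration in one design cell
#'
#' Returns the model-implied linear effect of anaesthesia duration (per
#' minute) in a given (suppression x POD) cell — for quantifier models, per
#' microstate class. The estimate is the linear combination of coefficients
#' that the treatment coding implies for that cell (e.g. the bare duration
#' coefficient in the reference cell, and the sum duration +
#' duration:suppression + duration:POD + duration:suppression:POD in the
#' suppression/POD cell of a descriptor model), with a Satterthwaite CI and
#' p-value via [lmerTest::contest1D()].
#'
#' @param model A [fit_trend_model()] result.
#' @param pod,suppression Logical cell selectors.
#' @param class Microstate class label (quantifier models only).
#' @param level Confidence level (default 0.95).
#' @return One-row `data.frame`: `pod`, `suppression`, (`class`,) `estimate`,
#'   `se`, `df`, `lower`, `upper`, `p`.
#' @export
contrast_slopes <- function(model, pod, suppression, class = NULL, level = 0.95) {
  stopifnot(inherits(model, "trend_model"), is_flag(pod), is_flag(suppression))
  if (model$kind == "descriptor" && !is.null(class)) {
    stop("descriptor models have no `class` term", call. = FALSE)
  }
  if (suppression && !model$has_suppression) {
    stop("the model has no suppression term; requested cell is undefined",
         call. = FALSE)
  }
  nd <- cell_newdata(model, c(0, 1), suppression, pod, class)
  tt <- delete.response(terms(model$fit, fixed.only = TRUE))
  x_full <- model.matrix(tt, nd)
  kept <- names(lme4::fixef(model$fit))
  l_full <- x_full[2L, ] - x_full[1L, ]
  if (any(l_full[setdiff(colnames(x_full), kept)] != 0)) {
    stop("cell slope loads on a rank-deficient (dropped) coefficient; ",
         "the contrast is inestimable in this design", call. = FALSE)
  }
  l <- as.numeric(l_full[kept])
  ct <- lmerTest::contest1D(model$fit, l, confint = TRUE, level = level)
  out <- data.frame(pod = pod, suppression = suppression,
                    estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df,
                    lower = ct$lower, upper = ct$upper, p = ct$`Pr(>|t|)`)
  if (!is.null(class)) out <- cbind(out[1:2], class = class, out[-(1:2)])
  out
}

#' Model-predicted trajectories over anaesthesia duration
#'
#' Model-implied mean response on a grid of anaesthesia durations for each
#' requested (suppression x POD) cell (x class for quantifier models), with a
#' Wald confidence band on the fixed-effects prediction; covariates are held
#' at reference levels (factors) or sample means (numerics). Grid points
#' outside the observed duration range are flagged `extrapolated`, not
#' refused.
#'
#' @param model A [fit_trend_model()] result.
#' @param durations Numeric grid in minutes (default 25 points over the
#'   observed range).
#' @param cells Optional `data.frame` with logical columns `pod` and
#'   `suppression` (and `class` for quantifier models); defaults to all
#'   combinations.
#' @param level Confidence level (default 0.95).
#' @return Plot-ready `data.frame`: cell columns, `mean_time`, `predicted`,
#'   `lower`, `upper`, `extrapolated`.
#' @export
predicted_trajectories <- function(model, durations = NULL, cells = NULL,
                                   level = 0.95) {
  stopifnot(inherits(model, "trend_model"))
  rng <- range(model$data$mean_time)
  durations <- durations %||% seq(rng[1L], rng[2L], length.out = 25L)
  if (is.null(cells)) {
    cells <- expand.grid(pod = c(FALSE, TRUE),
                         suppression = if (model$has_suppression) {
                           c(FALSE, TRUE)
                         } else FALSE)
    if (model$kind == "quantifier") {
      cells <- merge(cells, data.frame(class = levels(model$data$class)))
    }
  }
  beta <- lme4::fixef(model$fit)
  v <- as.matrix(vcov(model$fit))
  z <- qnorm(1 - (1 - level) / 2)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    nd <- cell_newdata(model, durations, cells$suppression[i], cells$pod[i],
                       if (model$kind == "quantifier") as.character(cells$class[i]))
    x <- fixed_model_matrix(model, nd)
    pred <- as.numeric(x %*% beta)
    se <- sqrt(rowSums((x %*% v) * x))
    out[[i]] <- cbind(cells[rep(i, length(durations)), , drop = FALSE],
                      data.frame(mean_time = durations, predicted = pred,
                                 lower = pred - z * se, upper = pred + z * se,
                                 extrapolated = durations < rng[1L] | durations > rng[2L]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# TANOVA: randomization statistics on scalp map topographies.

tanova_effects <- function() {
  c("class", "suppression", "pod", "class:suppression", "class:pod",
    "suppression:pod", "class:suppression:pod")
}

# Cell-mean array (class x suppression x pod-group x channel) from the
# subject map array, with equal weight per subject within group. An empty
# group (single-group designs; only within effects are then testable) is
# filled with the overall mean so it contributes nothing to within effects.
tanova_cell_means <- function(maps, pod) {
  k <- dim(maps)[2L]; s <- dim(maps)[3L]; ch <- dim(maps)[4L]
  m <- array(NA_real_, c(k, s, 2L, ch))
  overall <- apply(maps, c(2, 3, 4), mean)
  for (g in 1:2) {
    idx <- which(pod == (g == 2L))
    m[, , g, ] <- if (length(idx) == 0L) {
      overall
    } else {
      apply(maps[idx, , , , drop = FALSE], c(2, 3, 4), mean)
    }
  }
  m
}

# ANOVA effect topographies by inclusion-exclusion over marginal means;
# statistic = RMS over effect-level combinations of the effect map's GFP.
tanova_statistic <- function(cellmeans, factors) {
  dims <- c(class = 1L, suppression = 2L, pod = 3L)
  involved <- dims[factors]
  # marginal mean over the factor dims not in `keep` (channel dim kept)
  margin <- function(keep) apply(cellmeans, c(keep, 4L), mean)
  lv <- dim(cellmeans)[involved]
  combos <- expand.grid(lapply(lv, seq_len))
  total <- 0
  subsets <- lapply(0:(2^length(involved) - 1L), function(mask) {
    involved[bitwAnd(mask, 2^(seq_along(involved) - 1L)) > 0L]
  })
  marg <- lapply(subsets, margin)
  names(marg) <- vapply(subsets, function(s) paste(s, collapse = ","), character(1))
  for (ci in seq_len(nrow(combos))) {
    lev <- as.integer(combos[ci, ])
    eff <- 0
    for (si in seq_along(subsets)) {
      s <- subsets[[si]]
      sgn <- (-1)^(length(involved) - length(s))
      m <- marg[[si]]
      if (length(s) == 0L) {
        vec <- m                     # grand mean map (vector over channels)
      } else {
        lev_s <- lev[match(s, involved)]   # m has dims lv[s] x ch
        vec <- do.call(`[`, c(list(m), as.list(lev_s), list(TRUE)))
      }
      eff <- eff + sgn * vec
    }
    total <- total + gfp(eff)^2
  }
  sqrt(total / nrow(combos))
}

permute_within <- function(maps, factors) {
  n <- dim(maps)[1L]
  k <- dim(maps)[2L]
  out <- maps
  for (i in seq_len(n)) {
    if ("class" %in% factors && "suppression" %in% factors) {
      # permute the joint class x suppression cells
      flat <- matrix(maps[i, , , ], nrow = k * 2L)
      perm <- sample.int(k * 2L)
      out[i, , , ] <- array(flat[perm, ], c(k, 2L, dim(maps)[4L]))
    } else if ("class" %in% factors) {
      out[i, , , ] <- maps[i, sample.int(k), , , drop = FALSE]
    } else if ("suppression" %in% factors) {
      out[i, , , ] <- maps[i, , sample.int(2L), , drop = FALSE]
    }
  }
  out
}

#' Topographic ANOVA (TANOVA) on microstate maps
#'
#' Randomization test for systematic differences between scalp map
#' topographies in a design with microstate class and suppression as
#' within-subject factors and subsequent POD as the between-subject factor
#' (in the study, run on each patient's first EEG intervals). Maps are
#' GFP-normalized; for each effect the observed statistic is the root mean
#' square, over the effect's level combinations, of the GFP of the
#' ANOVA-style effect topography (for a two-level effect this is equivalent
#' to the GFP of the difference of the cell-mean maps). The null is built by
#' permuting within-subject condition labels per subject (within effects)
#' and/or group labels across subjects (between effects);
#' `p = (count of null >= observed + 1) / (n_permutations + 1)`.
#'
#' @param maps 4-d array `subject x class x suppression(2) x channel` of
#'   average-referenced maps (one map per patient per cell).
#' @param pod Logical per-subject POD status.
#' @param n_permutations Number of label permutations (default 999; the
#'   attainable p resolution is `1/(n_permutations + 1)`).
#' @param seed Optional integer seed.
#' @param effects Effects to test (default all mains and interactions).
#' @return An object of class `tanova_result`: `data.frame` with `effect`,
#'   `observed`, `p`, `n_permutations`.
#' @export
tanova <- function(maps, pod, n_permutations = 999L, seed = NULL,
                   effects = tanova_effects()) {
  stopifnot(length(dim(maps)) == 4L, dim(maps)[3L] == 2L,
            length(pod) == dim(maps)[1L])
  pod <- as.logical(pod)
  effects <- match.arg(effects, tanova_effects(), several.ok = TRUE)
  if (any(grepl("pod", effects)) && (sum(pod) < 2L || sum(!pod) < 2L)) {
    stop("need at least 2 patients per POD group for between-subject effects",
         call. = FALSE)
  }
  # GFP-normalize each map
  for (i in seq_len(dim(maps)[1L])) {
    for (c_ in seq_len(dim(maps)[2L])) {
      for (s_ in 1:2) {
        g <- gfp(maps[i, c_, s_, ])
        if (g > 0) maps[i, c_, s_, ] <- maps[i, c_, s_, ] / g
      }
    }
  }
  res <- with_seed(seed, {
    rows <- list()
    for (eff in effects) {
      factors <- strsplit(eff, ":", fixed = TRUE)[[1L]]
      obs <- tanova_statistic(tanova_cell_means(maps, pod), factors)
      within <- intersect(factors, c("class", "suppression"))
      between <- "pod" %in% factors
      null_ge <- 0L
      for (b in seq_len(n_permutations)) {
        pm <- if (length(within) > 0L) permute_within(maps, within) else maps
        pp <- if (between) sample(pod) else pod
        stat <- tanova_statistic(tanova_cell_means(pm, pp), factors)
        if (stat >= obs) null_ge <- null_ge + 1L
      }
      rows[[eff]] <- data.frame(effect = eff, observed = obs,
                                p = (null_ge + 1L) / (n_permutations + 1L),
                                n_permutations = n_permutations)
    }
    do.call(rbind, rows)
  })
  rownames(res) <- NULL
  structure(res, class = c("tanova_result", "data.frame"))
}

#' @export
print.tanova_result <- function(x, ...) {
  cat("<tanova_result>\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Channel-wise t-maps comparing two map conditions
#'
#' Per-electrode t statistics of the difference between two sets of scalp
#' maps (e.g. non-suppression vs suppression grand means across patients).
#' Paired by default (matched subjects); `paired = FALSE` uses Welch's t.
#'
#' @param maps_a,maps_b Matrices `subjects x channels`.
#' @param paired Matched subjects (default `TRUE`; rows must align).
#' @return Numeric vector of per-channel t values.
#' @export
channel_t_map <- function(maps_a, maps_b, paired = TRUE) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (ncol(maps_a) != ncol(maps_b)) stop("channel counts differ", call. = FALSE)
  if (paired) {
    if (nrow(maps_a) != nrow(maps_b)) {
      stop("paired t-maps need matched subjects", call. = FALSE)
    }
    if (nrow(maps_a) < 2L) stop("need at least 2 pairs", call. = FALSE)
    d <- maps_a - maps_b
    colMeans(d) / (apply(d, 2L, sd) / sqrt(nrow(d)))
  } else {
    if (nrow(maps_a) < 2L || nrow(maps_b) < 2L) {
      stop("need at least 2 subjects per condition", call. = FALSE)
    }
    va <- apply(maps_a, 2L, var) / nrow(maps_a)
    vb <- apply(maps_b, 2L, var) / nrow(maps_b)
    (colMeans(maps_a) - colMeans(maps_b)) / sqrt(va + vb)
  }
}
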