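pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulation = list(
      n_channels = 19L, n_classes = 4L, sampling_rate = 250,
      epoch_length = 2.5, epochs_per_set = 24L,
      mean_state_duration = 100, duration_shape = 2, carrier_freq = 10,
      snr = 5, gain = 30, suppression_amplitude = 5,
      n_patients = 8L, pod_fraction = 0.29, intervals_per_patient = 4L,
      suppression_fraction = 1 / 3, interval_spacing = 30,
      group_effects = zero_group_effects()
    ),
    preprocessing = list(
      band = c(2, 20), suppression_threshold = 10,
      epochs_per_set = 24L, max_span = 15, min_epochs = 2L,
      filter = TRUE
    ),
    microstates = list(n_classes = 4L, restarts = 10L, min_datasets = 2L),
    stats = list(n_permutations = 999L, random_slope = FALSE)
  )
}

check_keys <- function(x, template, path = "") {
  bad <- setdiff(names(x), names(template))
  if (length(bad) > 0L) {
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(x)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      check_keys(as.list(x[[nm]]), template[[nm]], paste0(path, nm, "$"))
    }
  }
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
                          is.list(user[[nm]])) {
      merge_config(defaults[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds the single configuration document that drives [run_pipeline()]:
#' simulation parameters (see [simulation_config()] and [simulate_cohort()]),
#' preprocessing band and suppression threshold, clustering settings, model
#' and permutation settings, and the global seed. Unknown keys are rejected.
#' The object serializes losslessly to JSON.
#'
#' @param ... Named overrides of the defaults, possibly nested lists (e.g.
#'   `simulation = list(n_patients = 12)`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defaults <- pipeline_defaults()
  check_keys(user, defaults)
  cfg <- merge_config(defaults, user)
  ge <- cfg$simulation$group_effects
  cfg$simulation$group_effects <- lapply(ge, function(v) {
    v <- unlist(v)
    setNames(as.numeric(v), names(v))
  })
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE, digits = NA))
  cat("\n")
  invisible(x)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return [read_pipeline_config()] returns a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  # named numeric vectors serialize as JSON arrays (names lost); store the
  # per-cell effect slopes as objects instead
  cfg$simulation$group_effects <- lapply(cfg$simulation$group_effects, as.list)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(sprintf("pipeline aborted in stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(out_dir, ".partial"))
    }
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> microstates -> quantifiers ->
#' statespace -> stats on a synthetic cohort and (optionally) writes all
#' result tables plus a manifest to `out_dir`. Rerunning with the same
#' configuration reproduces identical tables.
#'
#' Stages: (1) simulate the cohort from the config seed; (2) band-pass
#' filter, average-reference, re-detect suppression and assemble epoch sets;
#' (3) cluster GFP-peak maps per set, average hierarchically (set solutions
#' -> per-POD-group time-conditional means -> grand mean) and label against
#' the packaged templates; (4) back-fit and compute the quantifier table; (5)
#' compute the state space descriptor table; (6) fit the six trend models,
#' per-cell slope contrasts and predicted trajectories, and run the TANOVA on
#' first-interval maps. If only one suppression status survives
#' preprocessing (e.g. `suppression_threshold = 0`), the models degrade to
#' the 2-cell duration-by-POD design and the TANOVA is skipped.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for CSV/JSON results (optional).
#' @return Invisible list with the cohort, epoch sets, grand-mean solution,
#'   `quantifiers` and `descriptors` tables, fitted `models`, `contrasts`,
#'   `trajectories`, and `tanova` results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- config$simulation
  cohort <- run_stage("simulate", out_dir, {
    scfg <- simulation_config(
      n_channels = sim$n_channels, n_classes = sim$n_classes,
      sampling_rate = sim$sampling_rate, epoch_length = sim$epoch_length,
      epochs_per_set = sim$epochs_per_set,
      mean_state_duration = sim$mean_state_duration,
      duration_shape = sim$duration_shape, carrier_freq = sim$carrier_freq,
      snr = sim$snr, gain = sim$gain,
      suppression_amplitude = sim$suppression_amplitude, seed = config$seed)
    simulate_cohort(scfg, n_patients = sim$n_patients,
                    pod_fraction = sim$pod_fraction,
                    intervals_per_patient = sim$intervals_per_patient,
                    suppression_fraction = sim$suppression_fraction,
                    group_effects = sim$group_effects,
                    interval_spacing = sim$interval_spacing)
  })

  pp <- config$preprocessing
  sets <- run_stage("preprocess", out_dir, {
    all_sets <- list()
    for (p in cohort$patients) {
      eps <- lapply(p$epochs, function(e) {
        if (isTRUE(pp$filter)) e <- bandpass_filter(e, pp$band[1L], pp$band[2L])
        e <- average_reference(e)
        e$suppression <- detect_suppression(e, pp$suppression_threshold)
        e
      })
      all_sets <- c(all_sets,
                    assemble_intervals(eps, epochs_per_set = pp$epochs_per_set,
                                       max_span = pp$max_span,
                                       min_epochs = pp$min_epochs,
                                       patient_id = p$meta$patient_id))
    }
    all_sets
  })

  ms <- config$microstates
  micro <- run_stage("microstates", out_dir, {
    solutions <- vector("list", length(sets))
    for (i in seq_along(sets)) {
      maps <- do.call(rbind, lapply(sets[[i]]$epochs, function(e) {
        pk <- find_gfp_peaks(e)
        t(e$data[, pk, drop = FALSE])
      }))
      solutions[[i]] <- modified_kmeans(maps, n_classes = ms$n_classes,
                                        restarts = ms$restarts,
                                        seed = config$seed + i)
    }
    pod_by_pat <- setNames(cohort$meta$pod, cohort$meta$patient_id)
    group <- pod_by_pat[vapply(sets, function(s) s$patient_id, character(1))]
    time_bin <- round(vapply(sets, function(s) s$mean_time, numeric(1)) /
                        sim$interval_spacing)
    gm <- grand_mean_maps(solutions, group = group, time_bin = time_bin,
                          min_datasets = ms$min_datasets)
    grand <- gm$grand
    if (ncol(grand$class_maps) == 19L && nrow(grand$class_maps) == 4L) {
      grand <- label_by_template(grand, normative_templates())
    }
    list(solutions = solutions, group_means = gm$group_means, grand = grand)
  })

  quant <- run_stage("quantifiers", out_dir, quantifier_table(sets, micro$grand))
  desc <- run_stage("statespace", out_dir, descriptor_table(sets))

  st <- config$stats
  stats_out <- run_stage("stats", out_dir, {
    meta <- cohort$meta
    qtab <- merge(quant, meta, by = "patient_id", sort = FALSE)
    dtab <- merge(desc, meta, by = "patient_id", sort = FALSE)
    models <- list()
    contrasts <- list()
    trajectories <- list()
    two_cell <- length(unique(quant$suppression)) < 2L
    for (resp in c("duration_ms", "occurrence_per_s", "gfp_uv")) {
      models[[resp]] <- fit_trend_model(qtab, resp, kind = "quantifier",
                                        random_slope = st$random_slope)
    }
    for (resp in c("sigma", "phi", "omega")) {
      models[[resp]] <- fit_trend_model(dtab, resp, kind = "descriptor",
                                        random_slope = st$random_slope)
    }
    cells <- expand.grid(pod = c(FALSE, TRUE),
                         suppression = if (two_cell) FALSE else c(FALSE, TRUE))
    for (resp in names(models)) {
      m <- models[[resp]]
      rows <- list()
      for (i in seq_len(nrow(cells))) {
        if (m$kind == "quantifier") {
          for (cl in levels(m$data$class)) {
            rows[[length(rows) + 1L]] <-
              contrast_slopes(m, cells$pod[i], cells$suppression[i], class = cl)
          }
        } else {
          rows[[length(rows) + 1L]] <-
            contrast_slopes(m, cells$pod[i], cells$suppression[i])
        }
      }
      contrasts[[resp]] <- cbind(response = resp, with_class_col(do.call(rbind, rows)))
      traj <- predicted_trajectories(m, cells = cells_for_traj(m, cells))
      trajectories[[resp]] <- cbind(response = resp, with_class_col(traj))
    }
    tanova_res <- first_interval_tanova(sets, micro, meta, st$n_permutations,
                                        config$seed)
    list(models = models,
         contrasts = do.call(rbind, contrasts),
         trajectories = do.call(rbind, trajectories),
         tanova = tanova_res)
  })

  result <- list(cohort = cohort, sets = sets, solutions = micro$solutions,
                 grand = micro$grand, quantifiers = quant, descriptors = desc,
                 models = stats_out$models, contrasts = stats_out$contrasts,
                 trajectories = stats_out$trajectories,
                 tanova = stats_out$tanova, config = config)

  if (!is.null(out_dir)) {
    run_stage("write", out_dir, write_pipeline_outputs(result, out_dir))
  }
  invisible(result)
}

# Descriptor tables get a placeholder class column so quantifier and
# descriptor results stack into one table.
with_class_col <- function(df) {
  if (!"class" %in% names(df)) df$class <- NA_character_
  df
}

cells_for_traj <- function(model, cells) {
  if (model$kind == "quantifier") {
    merge(cells, data.frame(class = levels(model$data$class)))
  } else {
    cells
  }
}

# First-interval TANOVA inputs: each patient's earliest non-suppression and
# earliest suppression set solutions, aligned (permutation + polarity) to the
# grand mean so class k means the same topography across patients.
first_interval_tanova <- function(sets, micro, meta, n_permutations, seed) {
  pids <- vapply(sets, function(s) s$patient_id, character(1))
  supp <- vapply(sets, function(s) s$suppression, logical(1))
  times <- vapply(sets, function(s) s$mean_time, numeric(1))
  grand_maps <- micro$grand$class_maps
  k <- nrow(grand_maps)
  ch <- ncol(grand_maps)
  subj_maps <- list()
  subj_pod <- logical(0)
  for (pid in unique(pids)) {
    cube <- array(NA_real_, c(k, 2L, ch))
    ok <- TRUE
    for (s_ in 1:2) {
      idx <- which(pids == pid & supp == (s_ == 2L))
      if (length(idx) == 0L) { ok <- FALSE; break }
      first <- idx[which.min(times[idx])]
      sol <- unit_rows(micro$solutions[[first]]$class_maps)
      al <- best_alignment(unit_rows(grand_maps), sol)
      cube[, s_, ] <- al$signs * sol[al$perm, , drop = FALSE]
    }
    if (!ok) next
    subj_maps[[pid]] <- cube
    subj_pod <- c(subj_pod, meta$pod[meta$patient_id == pid])
  }
  if (length(subj_maps) < 4L || sum(subj_pod) < 2L || sum(!subj_pod) < 2L) {
    return(NULL)
  }
  maps <- array(NA_real_, c(length(subj_maps), k, 2L, ch))
  for (i in seq_along(subj_maps)) maps[i, , , ] <- subj_maps[[i]]
  tanova(maps, subj_pod, n_permutations = n_permutations, seed = seed)
}

#' Hierarchical grand-mean microstate maps
#'
#' Implements the hierarchical averaging scheme of the microstate stage:
#' per-interval solutions are averaged (polarity- and permutation-aligned)
#' within each (group x time-bin) cell that holds at least `min_datasets`
#' solutions, and the surviving time-conditional group means are averaged
#' into the grand mean.
#'
#' @param solutions List of [microstate_solution()]s (one per epoch set).
#' @param group Per-solution group label (e.g. POD status).
#' @param time_bin Per-solution time bin index.
#' @param min_datasets Minimum solutions per cell (default 2).
#' @return List with `group_means` (named list of solutions) and `grand`.
#' @export
grand_mean_maps <- function(solutions, group, time_bin, min_datasets = 2L) {
  stopifnot(length(solutions) == length(group),
            length(solutions) == length(time_bin))
  keys <- paste(group, time_bin, sep = "@")
  group_means <- list()
  for (key in unique(keys)) {
    sub <- solutions[keys == key]
    gm <- tryCatch(align_and_average(sub, min_datasets = min_datasets),
                   eegstates_exclusion = function(e) NULL)
    if (!is.null(gm)) group_means[[key]] <- gm
  }
  if (length(group_means) == 0L) {
    stop("no (group x time) cell reached the minimum number of data sets",
         call. = FALSE)
  }
  grand <- if (length(group_means) == 1L) {
    group_means[[1L]]
  } else {
    align_and_average(group_means, min_datasets = 1L)
  }
  list(group_means = group_means, grand = grand)
}

write_pipeline_outputs <- function(result, out_dir) {
  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(result$config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stamp <- function(df) {
    df$config_hash <- cfg_hash
    df
  }
  write.csv(stamp(result$quantifiers), file.path(out_dir, "quantifiers.csv"),
            row.names = FALSE)
  write.csv(stamp(result$descriptors), file.path(out_dir, "descriptors.csv"),
            row.names = FALSE)
  write.csv(stamp(result$cohort$meta), file.path(out_dir, "meta.csv"),
            row.names = FALSE)
  cm <- result$grand$class_maps
  write.csv(stamp(data.frame(class = rownames(cm), cm, check.names = FALSE)),
            file.path(out_dir, "class_maps.csv"), row.names = FALSE)
  coefs <- do.call(rbind, lapply(names(result$models), function(nm) {
    cbind(response = nm, result$models[[nm]]$coefficients)
  }))
  write.csv(stamp(coefs), file.path(out_dir, "coefficients.csv"), row.names = FALSE)
  write.csv(stamp(result$contrasts), file.path(out_dir, "contrasts.csv"),
            row.names = FALSE)
  write.csv(stamp(result$trajectories), file.path(out_dir, "trajectories.csv"),
            row.names = FALSE)
  if (!is.null(result$tanova)) {
    jsonlite::write_json(list(config_hash = cfg_hash,
                              table = as.data.frame(result$tanova)),
                         file.path(out_dir, "tanova.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package = "eegstates",
    version = as.character(utils::packageVersion("eegstates")),
    seed = result$config$seed,
    config_hash = cfg_hash,
    outputs = c("config.json", "meta.csv", "quantifiers.csv", "descriptors.csv",
                "class_maps.csv", "coefficients.csv", "contrasts.csv",
                "trajectories.csv",
                if (!is.null(result$tanova)) "tanova.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (file.exists(file.path(out_dir, ".partial"))) {
    unlink(file.path(out_dir, ".partial"))
  }
  invisible(out_dir)
}
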