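# Plain-text persistence of synthetic cohorts: CSV signal/metadata tables
# plus a JSON ground-truth sidecar.

rle_encode <- function(states) {
  r <- rle(states)
  paste(sprintf("%d:%d", r$values, r$lengths), collapse = ",")
}

rle_decode <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  unlist(lapply(parts, function(p) rep.int(as.integer(p[1L]), as.integer(p[2L]))))
}

#' Write a synthetic cohort to disk
#'
#' Persists a cohort as plain-text files in `dir`: `meta.csv` (patient
#' covariates), `epochs.csv` (one row per epoch: patient, index, onset,
#' suppression flag, duration), one `signals_<patient>.csv` per patient
#' (long-format sample table, one column per channel), and `truth.json`
#' (generator config, class maps, per-interval generating parameters and
#' run-length-encoded ground-truth state sequences).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  ep_rows <- list()
  for (p in cohort$patients) {
    pid <- p$meta$patient_id
    sig_rows <- list()
    for (e in seq_along(p$epochs)) {
      ep <- p$epochs[[e]]
      ep_rows[[length(ep_rows) + 1L]] <- data.frame(
        patient_id = pid, epoch = e, onset_min = ep$onset,
        suppression = ep$suppression, duration_s = ep$duration)
      m <- t(ep$data)
      colnames(m) <- ep$channel_labels %||% paste0("ch", seq_len(ncol(m)))
      sig_rows[[e]] <- data.frame(epoch = e, sample = seq_len(nrow(m)), m,
                                  check.names = FALSE)
    }
    write.csv(do.call(rbind, sig_rows),
              file.path(dir, sprintf("signals_%s.csv", pid)), row.names = FALSE)
  }
  write.csv(do.call(rbind, ep_rows), file.path(dir, "epochs.csv"),
            row.names = FALSE)
  truth <- list(
    config = unclass(cohort$config),
    class_maps = cohort$truth$class_maps,
    group_effects = cohort$truth$group_effects,
    intervals = cohort$truth$intervals,
    states = lapply(cohort$truth$states, function(per_pat) {
      vapply(per_pat, rle_encode, character(1))
    })
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic cohort from disk
#'
#' Inverse of [write_cohort()]; reconstructs the cohort, including ground
#' truth, from the plain-text files.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `synthetic_cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  epochs_tab <- read.csv(file.path(dir, "epochs.csv"), stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  cfg <- do.call(simulation_config, truth$config)
  patients <- vector("list", nrow(meta))
  states <- list()
  for (i in seq_len(nrow(meta))) {
    pid <- meta$patient_id[i]
    sig <- read.csv(file.path(dir, sprintf("signals_%s.csv", pid)),
                    check.names = FALSE)
    etab <- epochs_tab[epochs_tab$patient_id == pid, ]
    eps <- vector("list", nrow(etab))
    for (e in seq_len(nrow(etab))) {
      m <- t(as.matrix(sig[sig$epoch == etab$epoch[e],
                           -(1:2), drop = FALSE]))
      eps[[e]] <- eeg_epoch(m, cfg$sampling_rate, onset = etab$onset_min[e],
                            suppression = etab$suppression[e],
                            channel_labels = rownames(m))
    }
    patients[[i]] <- list(meta = meta[i, ], epochs = eps)
    states[[pid]] <- lapply(truth$states[[pid]], rle_decode)
  }
  structure(
    list(patients = patients, meta = meta,
         truth = list(class_maps = as.matrix(truth$class_maps),
                      states = states,
                      intervals = truth$intervals,
                      group_effects = truth$group_effects),
         config = cfg),
    class = "synthetic_cohort"
  )
}
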