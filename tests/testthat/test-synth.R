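test_that("template maps are average-referenced, unit-norm and distinct", {
  cases <- list(c(19L, 1L), c(19L, 4L), c(10L, 3L))
  for (cs in cases) {
    m <- make_template_maps(cs[1], cs[2], seed = 1)
    expect_equal(dim(m), c(cs[2], cs[1]))
    expect_lt(max(abs(rowSums(m))), 1e-10)
    expect_equal(unname(sqrt(rowSums(m^2))), rep(1, cs[2]))
    if (cs[2] > 1) {
      r <- cor(t(m))
      expect_lte(max(abs(r[upper.tri(r)])), 0.7)
    }
  }
  # identical seed, identical maps
  expect_identical(make_template_maps(19, 4, seed = 7),
                   make_template_maps(19, 4, seed = 7))
})

test_that("too many classes for the montage is a dimensionality error", {
  expect_error(make_template_maps(3, 3), "span only 2 dimensions")
  expect_error(simulation_config(n_channels = 3, n_classes = 3), "n_classes")
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(mean_state_duration = 0), "positive")
  expect_error(simulation_config(sampling_rate = 250, epoch_length = 2.501),
               "integer sample count")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("segment lengths follow the configured gamma mean", {
  set.seed(42)
  fs <- 250
  lens <- integer(0)
  while (length(lens) < 1000) {
    s <- eegstates:::draw_state_sequence(1e5, 4, 100 / 1000 * fs, shape = 2)
    lens <- c(lens, s$segments$length)
  }
  mean_ms <- mean(lens[1:1000]) * 1000 / fs
  expect_lt(abs(mean_ms - 100) / 100, 0.05)
})

test_that("noise-free single-class epochs have peak maps equal to the class map", {
  cfg <- simulation_config(snr = 1e9, seed = 1)
  tm <- orthogonal_maps(19, 4, seed = 2)
  set.seed(3)
  se <- simulate_epoch(cfg, tm, forced_class = 3)
  ep <- average_reference(se$epoch)
  pk <- find_gfp_peaks(ep)
  rs <- apply(ep$data[, pk, drop = FALSE], 2,
              function(v) spatial_correlation(v, tm[3, ], ignore_polarity = TRUE))
  expect_true(all(rs > 0.999))
  expect_true(all(se$states == 3L))
})

test_that("suppression epochs are rescaled below the detection threshold", {
  cfg <- simulation_config(seed = 1)
  tm <- orthogonal_maps(19, 4, seed = 2)
  set.seed(4)
  se <- simulate_epoch(cfg, tm, suppression = TRUE)
  ptp <- max(apply(se$epoch$data, 1, function(ch) diff(range(ch))))
  expect_equal(ptp, 5, tolerance = 1e-9)
  expect_true(detect_suppression(se$epoch))
  # same config without suppression is well above threshold
  set.seed(4)
  se2 <- simulate_epoch(cfg, tm, suppression = FALSE)
  expect_false(detect_suppression(se2$epoch))
})

test_that("cohort design counts and ordering honour the specification", {
  cfg <- simulation_config(sampling_rate = 100, epoch_length = 0.5,
                           epochs_per_set = 2L, seed = 9)
  cohort <- simulate_cohort(cfg, n_patients = 100L, pod_fraction = 0.29,
                            intervals_per_patient = 2L,
                            suppression_fraction = 0.5)
  expect_equal(sum(cohort$meta$pod), 29L)
  # interval mean times strictly increasing within patient
  iv <- cohort$truth$intervals
  for (pid in unique(iv$patient_id)) {
    expect_true(all(diff(iv$mean_time[iv$patient_id == pid]) > 0))
  }
  expect_error(simulate_cohort(cfg, n_patients = 2, intervals_per_patient = 1),
               "unidentifiable")
  # degenerate single-patient cohort is still a valid cohort
  one <- simulate_cohort(cfg, n_patients = 1L, pod_fraction = 0,
                         intervals_per_patient = 2L)
  expect_equal(length(one$patients), 1L)
})

test_that("identical seeds give identical cohorts", {
  cfg <- simulation_config(sampling_rate = 100, epoch_length = 0.5,
                           epochs_per_set = 2L, seed = 5)
  c1 <- simulate_cohort(cfg, n_patients = 3L, intervals_per_patient = 2L)
  c2 <- simulate_cohort(cfg, n_patients = 3L, intervals_per_patient = 2L)
  expect_identical(c1$meta, c2$meta)
  expect_identical(c1$patients[[2]]$epochs[[3]]$data,
                   c2$patients[[2]]$epochs[[3]]$data)
  expect_identical(c1$truth$states, c2$truth$states)
})

test_that("injected trends drift the generating parameters linearly in time", {
  ge <- zero_group_effects()
  ge$duration["supp1_pod1"] <- -0.2
  ge$gain["supp1_pod1"] <- 0.01
  cfg <- simulation_config(sampling_rate = 100, epoch_length = 0.5,
                           epochs_per_set = 2L, seed = 3)
  cohort <- simulate_cohort(cfg, n_patients = 8L, pod_fraction = 0.5,
                            intervals_per_patient = 4L,
                            suppression_fraction = 0.5, group_effects = ge)
  iv <- merge(cohort$truth$intervals, cohort$meta, by = "patient_id")
  cell <- iv[iv$suppression & iv$pod, ]
  other <- iv[!(iv$suppression & iv$pod), ]
  expect_equal(cell$true_duration_ms, 100 - 0.2 * cell$mean_time)
  expect_equal(other$true_duration_ms, rep(100, nrow(other)))
  expect_equal(cell$true_gain, 30 * (1 + 0.01 * cell$mean_time))
})

test_that("cohorts round-trip through the plain-text store", {
  cfg <- simulation_config(sampling_rate = 100, epoch_length = 0.5,
                           epochs_per_set = 2L, seed = 21)
  cohort <- simulate_cohort(cfg, n_patients = 2L, intervals_per_patient = 2L)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$meta, cohort$meta)
  expect_identical(back$truth$states, cohort$truth$states)
  expect_equal(back$patients[[1]]$epochs[[2]]$data,
               cohort$patients[[1]]$epochs[[2]]$data,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$patients[[2]]$epochs[[1]]$onset,
               cohort$patients[[2]]$epochs[[1]]$onset)
  expect_equal(as.matrix(back$truth$class_maps), cohort$truth$class_maps,
               tolerance = 1e-9, ignore_attr = TRUE)
})
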