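# Four orthogonal maps on 6 channels for hand-built epochs.
maps6 <- make_template_maps(6, 4, seed = 1)

test_that("back-fitting labels a pure single-class epoch uniformly", {
  cfg <- simulation_config(snr = 1e9, seed = 1)
  tm <- orthogonal_maps(19, 4, seed = 2)
  set.seed(3)
  se <- simulate_epoch(cfg, tm, forced_class = 2)
  labels <- backfit(average_reference(se$epoch), microstate_solution(tm))
  expect_true(all(labels == 2L))
})

test_that("non-peak samples inherit the nearest peak label, earlier peak on ties", {
  # peaks at samples 2 (class 1) and 8 (class 4); sample 5 is equidistant
  ep <- stepped_epoch(c(1, 3, 1, 1, 1, 1, 1, 3, 1),
                      c(1, 1, 1, 1, 1, 4, 4, 4, 4), maps6)
  expect_equal(find_gfp_peaks(ep), c(2L, 8L))
  labels <- backfit(ep, microstate_solution(maps6))
  expect_equal(labels, c(1L, 1L, 1L, 1L, 1L, 4L, 4L, 4L, 4L))
})

test_that("a peak equally correlated with two classes takes the lower label", {
  m <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1)) / sqrt(2)
  mix <- (m[1, ] + m[2, ]) / sqrt(2)
  ep <- stepped_epoch(c(1, 3, 1), c(1, 1, 1), rbind(mix, mix))
  labels <- backfit(ep, microstate_solution(m))
  expect_true(all(labels == 1L))
})

test_that("back-fitting is invariant to amplitude scaling", {
  cfg <- simulation_config(snr = 5, seed = 1)
  tm <- orthogonal_maps(19, 4, seed = 4)
  set.seed(5)
  ep <- average_reference(simulate_epoch(cfg, tm)$epoch)
  sol <- microstate_solution(tm)
  expect_identical(backfit(ep, sol), backfit(eegstates:::replace_data(ep, ep$data * 7), sol))
})

test_that("an epoch without GFP peaks raises the unlabelled signal", {
  flat <- eeg_epoch(matrix(rep(c(1, -1), 10), 2, 10, byrow = FALSE), 250)
  expect_error(backfit(flat, microstate_solution(rbind(c(1, -1), c(-1, 1)))),
               class = "eegstates_unlabelled")
})

test_that("segmentation discards runs touching either epoch edge", {
  x <- matrix(rnorm(16), 2)
  seg <- segment_and_filter(c(1, 1, 1, 2, 2, 2, 1, 1), x, sampling_rate = 250)
  expect_equal(nrow(seg$segments), 3L)
  expect_equal(seg$segments$truncated, c(TRUE, FALSE, TRUE))
  retained <- seg$segments[!seg$segments$truncated, ]
  expect_equal(retained$class, 2L)
  expect_equal(retained$length, 3L)

  uni <- segment_and_filter(rep(3L, 8), x, sampling_rate = 250)
  expect_equal(sum(!uni$segments$truncated), 0L)

  alt <- segment_and_filter(rep(c(1L, 2L), 5), matrix(rnorm(20), 2),
                            sampling_rate = 250)
  expect_equal(sum(!alt$segments$truncated), 8L)  # all interior length-1 runs
  expect_true(all(alt$segments$length == 1L))
})

test_that("segments partition the samples and adjacent segments differ", {
  set.seed(6)
  for (i in 1:10) {
    labels <- sample(1:4, 60, replace = TRUE)
    seg <- segment_and_filter(labels, matrix(rnorm(120), 2), sampling_rate = 250)
    expect_equal(sum(seg$segments$length), 60L)
    expect_true(all(diff(seg$segments$class) != 0))
  }
})

test_that("quantifier arithmetic matches the stated definitions", {
  # one retained 25-sample segment at 250 Hz -> 100 ms
  labels <- c(rep(1L, 5), rep(2L, 25), rep(1L, 595))
  seg <- segment_and_filter(labels, matrix(rnorm(2 * 625), 2), sampling_rate = 250)
  q <- compute_quantifiers(seg, n_classes = 4)
  expect_equal(q$duration_ms[q$class == "B"], 100)

  # 12 retained class-C segments in 6 s of analysed EEG -> occurrence 2.0 /s
  # 2 s at 250 Hz; four interior class-3 runs per epoch
  one_epoch_labels <- c(rep(1L, 10), rep(c(rep(3L, 30), rep(2L, 60)), 4),
                        rep(1L, 130))
  segs <- lapply(1:3, function(i) {
    segment_and_filter(one_epoch_labels, matrix(rnorm(1000), 2),
                       sampling_rate = 250)
  })
  stopifnot(sum(vapply(segs, function(s)
    sum(s$segments$class == 3 & !s$segments$truncated), integer(1))) == 12)
  q2 <- compute_quantifiers(segs, n_classes = 4)
  expect_equal(q2$occurrence_per_s[q2$class == "C"], 2)

  # a class never seen: missing duration/GFP, zero occurrence
  expect_true(is.na(q$duration_ms[q$class == "D"]))
  expect_true(is.na(q$gfp_uv[q$class == "D"]))
  expect_equal(q$occurrence_per_s[q$class == "D"], 0)
})

test_that("occurrence x duration summed over classes respects the coverage bound", {
  set.seed(7)
  for (i in 1:10) {
    labels <- sample(1:4, 250, replace = TRUE)
    seg <- segment_and_filter(labels, matrix(rnorm(500), 2), sampling_rate = 250)
    q <- compute_quantifiers(seg, n_classes = 4)
    load <- sum(q$occurrence_per_s * q$duration_ms, na.rm = TRUE)
    expect_lte(load, 1000 + 1e-9)
  }
})

test_that("quantifier tables aggregate per interval and class", {
  cfg <- simulation_config(snr = 20, epochs_per_set = 4L, seed = 2)
  tm <- orthogonal_maps(19, 4, seed = 8)
  set.seed(9)
  eps <- lapply(1:4, function(i) {
    e <- average_reference(simulate_epoch(cfg, tm, onset = 30 + i * 0.05)$epoch)
    e
  })
  sets <- assemble_intervals(eps, epochs_per_set = 4L, patient_id = "P1")
  tab <- quantifier_table(sets, microstate_solution(tm))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$class, microstate_labels <- c("A", "B", "C", "D"))
  expect_true(all(tab$duration_ms > 0, na.rm = TRUE))
  expect_true(all(tab$occurrence_per_s >= 0))
  expect_equal(unique(tab$patient_id), "P1")
})
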