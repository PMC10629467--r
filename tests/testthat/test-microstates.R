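test_that("gfp is the spatial standard deviation", {
  expect_equal(gfp(rep(0, 19)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  set.seed(1)
  v <- rnorm(19); v <- v - mean(v)
  expect_equal(gfp(3.5 * v), 3.5 * gfp(v))
  expect_equal(gfp(v), sqrt(mean(v^2)))
})

test_that("GFP peaks are strict interior local maxima", {
  # per-sample GFP (1,3,1,3,1) -> peaks at samples 2 and 4
  g <- rbind(c(1, 3, 1, 3, 1), -c(1, 3, 1, 3, 1)) / sqrt(2)
  expect_equal(find_gfp_peaks(g), c(2L, 4L))
  mono <- rbind(1:10, -(1:10))
  expect_length(find_gfp_peaks(mono), 0L)
  expect_error(find_gfp_peaks(matrix(1, 2, 2)), "3 samples")
})

test_that("an amplitude-modulated 10 Hz carrier has two GFP peaks per cycle", {
  fs <- 250
  t <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
  carrier <- (1 + 0.3 * sin(2 * pi * 0.8 * t)) * sin(2 * pi * 10 * t)
  x <- average_reference(outer(seq(-1, 1, length.out = 19), carrier))
  n_peaks <- length(find_gfp_peaks(x))
  expect_gte(n_peaks, 45)   # ~2 peaks x 10 Hz x 2.5 s = 50
  expect_lte(n_peaks, 55)
})

test_that("spatial correlation handles polarity and degenerate maps", {
  m <- orthogonal_maps(19, 2, seed = 3)
  expect_equal(spatial_correlation(m[1, ], m[1, ]), 1)
  expect_equal(spatial_correlation(m[1, ], -m[1, ], ignore_polarity = TRUE), 1)
  expect_equal(spatial_correlation(m[1, ], m[2, ]), 0, tolerance = 1e-10)
  expect_error(spatial_correlation(m[1, ], rep(2, 19)), "zero-variance")
})

test_that("modified k-means recovers noise-free templates despite polarity flips", {
  tm <- orthogonal_maps(19, 4, seed = 4)
  set.seed(5)
  flips <- sample(c(-1, 1), 120, replace = TRUE)
  maps <- tm[rep(1:4, 30), ] * flips
  sol <- modified_kmeans(maps, 4, seed = 6)
  expect_maps_match(sol$class_maps, tm, min_r = 0.999)
  expect_equal(sol$explained_variance, 1, tolerance = 1e-9)
  expect_error(modified_kmeans(tm[1:3, ], 4), "fewer maps")
})

test_that("k-means is deterministic given a seed and polarity-invariant", {
  cfg <- simulation_config(snr = 10, seed = 1)
  tm <- orthogonal_maps(19, 4, seed = 7)
  maps <- pooled_peak_maps(cfg, tm, n_epochs = 6, seed = 8)
  s1 <- modified_kmeans(maps, 4, seed = 9)
  s2 <- modified_kmeans(maps, 4, seed = 9)
  expect_identical(s1$class_maps, s2$class_maps)
  set.seed(10)
  flipped <- maps * sample(c(-1, 1), nrow(maps), replace = TRUE)
  s3 <- modified_kmeans(flipped, 4, seed = 9)
  r <- abs(cor(t(s3$class_maps), t(s1$class_maps)))
  expect_true(all(apply(r, 2, max) > 0.999))
})

test_that("duplicated identical maps give one dominant class, others degenerate", {
  tm <- orthogonal_maps(19, 4, seed = 11)
  maps <- tm[rep(1L, 40), ]
  sol <- modified_kmeans(maps, 4, seed = 12)
  expect_equal(sol$explained_variance, 1, tolerance = 1e-9)
  expect_equal(sum(sol$degenerate), 3L)
})

test_that("explained variance matches a direct projection oracle", {
  tm <- orthogonal_maps(19, 4, seed = 13)
  sol <- microstate_solution(tm)
  expect_equal(explained_variance(sol, tm), 1)
  # maps orthogonal to every class map explain nothing
  extra <- make_template_maps(19, 6, seed = 13)[5:6, ]
  expect_equal(explained_variance(sol, extra), 0, tolerance = 1e-12)
  # mixed case against brute force
  set.seed(14)
  x <- matrix(rnorm(50 * 19), 50)
  x <- x - rowMeans(x)
  oracle <- {
    tot <- sum(x^2)
    resid <- sum(vapply(seq_len(nrow(x)), function(i) {
      proj <- max((tm %*% x[i, ])^2)
      sum(x[i, ]^2) - proj
    }, numeric(1)))
    1 - resid / tot
  }
  expect_equal(explained_variance(sol, x), oracle)
})

test_that("explained variance is non-decreasing in the number of classes", {
  cfg <- simulation_config(snr = 5, seed = 2)
  tm <- orthogonal_maps(19, 4, seed = 15)
  maps <- pooled_peak_maps(cfg, tm, n_epochs = 6, seed = 16)
  evs <- vapply(2:5, function(k) {
    modified_kmeans(maps, k, restarts = 20, seed = 17)$explained_variance
  }, numeric(1))
  expect_true(all(diff(evs) > -1e-9))
})

test_that("aligned averaging is permutation- and polarity-invariant", {
  tm <- orthogonal_maps(19, 4, seed = 18)
  sol <- microstate_solution(tm)
  swapped <- microstate_solution(tm[c(2, 1, 4, 3), ])
  avg <- align_and_average(list(sol, swapped))
  expect_maps_match(avg$class_maps, tm, min_r = 0.999)
  flipped <- microstate_solution(-tm)
  avg2 <- align_and_average(list(sol, flipped))
  expect_maps_match(avg2$class_maps, tm, min_r = 0.999)
  expect_error(align_and_average(list(sol)), class = "eegstates_exclusion")
})

test_that("averaging perturbed solutions lands closer to truth than the median one", {
  tm <- orthogonal_maps(19, 4, seed = 19)
  set.seed(20)
  noisy <- lapply(1:10, function(i) {
    m <- tm + matrix(rnorm(76, sd = 0.35), 4)
    m <- m - rowMeans(m)
    perm <- sample(4)
    microstate_solution((m / sqrt(rowSums(m^2)))[perm, ] *
                          sample(c(-1, 1), 4, replace = TRUE))
  })
  avg <- align_and_average(noisy)
  fit <- function(sol_maps) {
    r <- abs(cor(t(sol_maps), t(tm)))
    mean(apply(r, 2, max))
  }
  singles <- vapply(noisy, function(s) fit(s$class_maps), numeric(1))
  expect_gt(fit(avg$class_maps), median(singles))
})

test_that("template labelling equals the brute-force permutation oracle", {
  templ <- normative_templates()
  sol <- microstate_solution(templ)
  lab <- label_by_template(sol, templ)
  expect_equal(lab$labels, c("A", "B", "C", "D"))
  expect_equal(unname(lab$template_correlations), rep(1, 4), tolerance = 1e-9)
  # A/B swap detected
  swapped <- microstate_solution(templ[c(2, 1, 3, 4), ])
  lab2 <- label_by_template(swapped, templ)
  expect_equal(lab2$class_maps[, 1], templ[, 1], ignore_attr = TRUE)
  expect_equal(rownames(lab2$class_maps), c("A", "B", "C", "D"))
  # noisy case: exhaustive search in test code over all 24 permutations
  set.seed(21)
  noisy <- templ + matrix(rnorm(76, sd = 0.4), 4)
  noisy <- noisy - rowMeans(noisy)
  solN <- microstate_solution(noisy)
  labN <- label_by_template(solN, templ)
  perms <- eegstates:::permutations(4)
  r <- abs(cor(t(templ), t(noisy)))
  scores <- apply(perms, 1, function(p) sum(r[cbind(1:4, p)]))
  best <- perms[which.max(scores), ]
  expect_equal(unname(labN$class_maps), unname(noisy[best, ]))
})
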