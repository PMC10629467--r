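test_that("a constant response gives zero slopes and the constant as intercept", {
  d <- simulate_trend_data("omega", "descriptor", n_patients = 12,
                           baseline = 5, sd_patient = 0, sd_resid = 0, seed = 1)
  m <- suppressWarnings(fit_trend_model(d, "omega", "descriptor"))
  cc <- m$coefficients
  expect_equal(cc$estimate[cc$term == "(Intercept)"], 5, tolerance = 1e-8)
  expect_lt(max(abs(cc$estimate[grepl("mean_time", cc$term)])), 1e-10)
})

test_that("the reference-cell contrast equals the raw duration coefficient", {
  d <- simulate_trend_data("sigma", "descriptor", n_patients = 16,
                           baseline = 300, sd_patient = 10, sd_resid = 5, seed = 2)
  m <- fit_trend_model(d, "sigma", "descriptor")
  cc <- m$coefficients
  ref <- contrast_slopes(m, pod = FALSE, suppression = FALSE)
  expect_identical(ref$estimate, cc$estimate[cc$term == "mean_time"])
})

test_that("cell contrasts are the Table-style sums of coefficient terms", {
  d <- simulate_trend_data("omega", "descriptor", n_patients = 16, seed = 3)
  m <- fit_trend_model(d, "omega", "descriptor")
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  # Supp+|POD+ descriptor cell: sum of all four duration terms
  expect_equal(contrast_slopes(m, pod = TRUE, suppression = TRUE)$estimate,
               sum(est[c("mean_time", "mean_time:suppressionyes",
                         "mean_time:podyes",
                         "mean_time:suppressionyes:podyes")]))
  # Supp+|POD- cell: duration + duration x suppression
  expect_equal(contrast_slopes(m, pod = FALSE, suppression = TRUE)$estimate,
               sum(est[c("mean_time", "mean_time:suppressionyes")]))

  # quantifier model: class-specific sums
  dq <- simulate_trend_data("duration_ms", "quantifier", n_patients = 16,
                            baseline = 100, sd_patient = 3, sd_resid = 3, seed = 4)
  mq <- fit_trend_model(dq, "duration_ms", "quantifier")
  estq <- setNames(mq$coefficients$estimate, mq$coefficients$term)
  got <- contrast_slopes(mq, pod = TRUE, suppression = TRUE, class = "B")$estimate
  want <- sum(estq[c("mean_time", "mean_time:suppressionyes", "mean_time:podyes",
                     "mean_time:classB", "mean_time:suppressionyes:podyes",
                     "mean_time:suppressionyes:classB", "mean_time:podyes:classB",
                     "mean_time:suppressionyes:podyes:classB")])
  expect_equal(got, want)
})

test_that("design preconditions are enforced", {
  d <- simulate_trend_data("omega", "descriptor", n_patients = 12,
                           pod_fraction = 0, seed = 5)
  expect_error(fit_trend_model(d, "omega", "descriptor"), "2 patients per POD")
  d2 <- simulate_trend_data("omega", "descriptor", n_patients = 12, seed = 6)
  d2 <- d2[!(d2$suppression & d2$pod), ]
  expect_error(fit_trend_model(d2, "omega", "descriptor"), "empty design cell")
})

test_that("single-level suppression degrades to the two-cell design", {
  d <- simulate_trend_data("omega", "descriptor", n_patients = 12,
                           suppression_fraction = 0, seed = 7)
  expect_message(m <- fit_trend_model(d, "omega", "descriptor"), "2-cell")
  expect_false(m$has_suppression)
  expect_silent(contrast_slopes(m, pod = TRUE, suppression = FALSE))
  expect_error(contrast_slopes(m, pod = TRUE, suppression = TRUE),
               "no suppression term")
})

test_that("predicted trajectories behave like the fitted fixed surface", {
  d <- simulate_trend_data("omega", "descriptor", n_patients = 16,
                           baseline = 8, sd_patient = 0.5, sd_resid = 0.5, seed = 8)
  m <- fit_trend_model(d, "omega", "descriptor", covariates = character(0))
  # flat model: no injected slopes -> near-flat trajectories
  tr <- predicted_trajectories(m)
  spread <- tapply(tr$predicted, interaction(tr$pod, tr$suppression),
                   function(v) diff(range(v)))
  expect_true(all(spread < 0.5))
  # at duration 0 in the reference cell the prediction is the intercept
  tr0 <- predicted_trajectories(m, durations = 0,
                                cells = data.frame(pod = FALSE, suppression = FALSE))
  expect_equal(tr0$predicted,
               m$coefficients$estimate[m$coefficients$term == "(Intercept)"])
  # bands widen away from the covariate centroid; extrapolation flagged
  centre <- mean(m$data$mean_time)
  grid <- c(centre, centre + 100, centre + 300, centre + 600)
  trw <- predicted_trajectories(m, durations = grid,
                                cells = data.frame(pod = FALSE, suppression = FALSE))
  widths <- trw$upper - trw$lower
  expect_true(all(diff(widths) > 0))
  expect_true(trw$extrapolated[4])
  expect_false(trw$extrapolated[1])
})

test_that("tanova p-values honour the permutation resolution", {
  set.seed(9)
  maps <- array(rnorm(8 * 4 * 2 * 19), c(8, 4, 2, 19))
  pod <- rep(c(TRUE, FALSE), 4)
  res <- tanova(maps, pod, n_permutations = 19, seed = 10)
  expect_true(all(res$p >= 1 / 20))
  expect_true(all(res$p <= 1))
  expect_error(tanova(maps, rep(FALSE, 8), n_permutations = 19),
               "2 patients per POD group")
})

test_that("tanova detects a group-specific class-D topography", {
  tm <- normative_templates()
  other <- make_template_maps(19, 5, seed = 11)[5, ]
  set.seed(12)
  n <- 16
  pod <- rep(c(FALSE, TRUE), each = n / 2)
  maps <- array(NA_real_, c(n, 4, 2, 19))
  for (i in seq_len(n)) {
    base <- tm
    if (pod[i]) base[4, ] <- other        # different class-D map in one group
    for (s in 1:2) maps[i, , s, ] <- base + matrix(rnorm(76, sd = 0.03), 4)
  }
  res <- tanova(maps, pod, n_permutations = 999, seed = 13,
                effects = c("class:pod", "suppression:pod"))
  expect_lte(res$p[res$effect == "class:pod"], 0.01)
  expect_gt(res$p[res$effect == "suppression:pod"], 0.05)
})

test_that("channel t-maps match the paired t formula and its symmetries", {
  set.seed(14)
  a <- matrix(rnorm(6 * 19), 6)
  expect_true(all(channel_t_map(a, a) == 0 | is.nan(channel_t_map(a, a))))
  b <- a + matrix(rnorm(6 * 19, sd = 0.5), 6)
  expect_equal(channel_t_map(a, b), -channel_t_map(b, a))
  # single-electrode offset against the hand formula
  delta <- 0.8
  b2 <- a
  b2[, 5] <- a[, 5] - delta + rnorm(6, sd = 0.1)
  d <- a - b2
  t5 <- mean(d[, 5]) / (sd(d[, 5]) / sqrt(6))
  expect_equal(channel_t_map(a, b2, paired = TRUE)[5], t5)
  expect_error(channel_t_map(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "at least 2")
})

test_that("anova table exposes both df conventions", {
  d <- simulate_trend_data("omega", "descriptor", n_patients = 12, seed = 15)
  m <- fit_trend_model(d, "omega", "descriptor")
  a_sat <- anova_table(m)
  expect_true("Pr(>F)" %in% colnames(a_sat))
  a_lme4 <- anova_table(m, ddf = "lme4")
  expect_false("Pr(>F)" %in% colnames(a_lme4))
})
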