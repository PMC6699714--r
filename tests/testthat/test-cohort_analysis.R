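test_that("curve normalization maps to 0-1000 time and unit length", {
  tr <- length_trajectory("n", c(0, 90, 180, 270), c(6, 6, 3, 0))
  ev <- analyze_trajectory(tr, literal_baseline())
  cv <- normalize_curve(tr, ev)
  expect_equal(cv$norm_times, c(0, 1000 / 3, 2000 / 3, 1000))
  expect_equal(cv$norm_lengths, c(1, 1, 0.5, 0))
  expect_equal(max(cv$norm_lengths), 1)
  expect_gte(cv$start_marker, 0)
  expect_lte(cv$start_marker, 1000)
  expect_error(normalize_curve(make_traj(rep(5, 5)),
                               analyze_trajectory(make_traj(rep(5, 5)),
                                                  literal_baseline())),
               "censored")
})

test_that("instant start markers cluster at the end of normalized time", {
  # flat construction: no drift, so curves hold full length to the drop
  cfg <- noiseless_config(n_control = 0, n_gradual = 0, n_instant = 20,
                          n_combined = 0, drift = 0, seed = 12)
  co <- simulate_cohort(cfg)
  res <- analyze_cohort(co$trajectories, baseline = literal_baseline())
  curves <- lapply(co$truth$cilium_id, function(id) {
    normalize_curve(co$trajectories[[id]],
                    res$events[res$events$cilium_id == id, ])
  })
  markers <- vapply(curves, function(cv) cv$start_marker, numeric(1))
  frames <- vapply(co$truth$cilium_id, function(id) {
    res$events$completion_index[res$events$cilium_id == id]
  }, numeric(1))
  # movies with >= 100 frames before completion put the start marker in
  # the last ~10 normalized units
  expect_true(all(markers[frames >= 100] >= 990))

  avg <- average_curves(curves)
  # instant curves stay near full length well past mid-movie
  expect_gte(avg$mean_lengths[which.min(abs(avg$grid - 500))], 0.95)
  expect_true(all(avg$mean_lengths >= 0 & avg$mean_lengths <= 1))
})

test_that("curve averaging is permutation-invariant and exact on singles", {
  grid <- seq(0, 1000, length.out = 101)
  c1 <- structure(list(norm_times = grid, norm_lengths = seq(1, 0, length.out = 101),
                       start_marker = 100), class = "normalized_curve")
  c2 <- structure(list(norm_times = grid, norm_lengths = rev(seq(1, 0, length.out = 101)),
                       start_marker = 900), class = "normalized_curve")
  one <- average_curves(list(c1), grid_n = 101L)
  expect_equal(one$mean_lengths, c1$norm_lengths)
  ab <- average_curves(list(c1, c2), grid_n = 101L)
  ba <- average_curves(list(c2, c1), grid_n = 101L)
  expect_equal(ab$mean_lengths, ba$mean_lengths)
  # mirror-symmetric curves average to the symmetry axis
  expect_equal(ab$mean_lengths, rep(0.5, 101))
  expect_error(average_curves(list()), "at least one")
})

test_that("class frequencies match reference cohort compositions", {
  fake <- function(counts) {
    data.frame(class = rep(names(counts), counts),
               stringsAsFactors = FALSE)
  }
  f1 <- class_frequencies(fake(c(gradual = 11, instant = 32,
                                 combined = 26)))
  expect_equal(f1$n, 69)
  expect_equal(sum(f1$frequencies), 1)
  expect_equal(round(100 * f1$instant_terminal, 1), 84.1)
  f2 <- class_frequencies(fake(c(gradual = 1, instant = 25,
                                 combined = 24)))
  expect_equal(100 * f2$instant_terminal, 98)
  f3 <- class_frequencies(fake(c(gradual = 1)))
  expect_equal(f3$instant_terminal, 0)
  expect_error(class_frequencies(data.frame(class = "censored")),
               "no classified")
})

test_that("rate statistics: identical, shifted and undersized samples", {
  ev <- data.frame(
    class = rep(c("gradual", "instant"), each = 3),
    gradual_rate_um_per_min = c(1, 2, 3, NA, NA, NA),
    instant_min_rate_um_per_min = c(NA, NA, NA, 1, 2, 3)
  )
  rs <- rate_statistics(ev)
  gi <- rs$tests[rs$tests$comparison == "gradual_only vs instant_only", ]
  expect_equal(gi$statistic, 0)
  expect_equal(gi$p, 1)
  # the combined-phase comparisons have no events and are skipped
  expect_warning(rate_statistics(ev), "skipped")

  ev2 <- ev
  ev2$instant_min_rate_um_per_min <- c(NA, NA, NA, 11, 12, 13)
  rs2 <- suppressWarnings(rate_statistics(ev2))
  gi2 <- rs2$tests[rs2$tests$comparison == "gradual_only vs instant_only", ]
  expect_lt(gi2$p, 0.01)
})

test_that("timing histograms bin starts and ends hourly", {
  ev <- data.frame(
    class = "instant",
    start_time_min = c(10, 70, 95),
    end_time_min = c(72, 95, 170)
  )
  h <- timing_histogram(ev)
  expect_equal(h$n_end, c(0L, 2L, 1L))
  expect_equal(h$n_start, c(1L, 2L, 0L))
  h0 <- timing_histogram(ev[0, ])
  expect_true(all(h0$n_start == 0) && all(h0$n_end == 0))
})

test_that("synthetic end points peak at 1-3 h under the default onsets", {
  co <- simulate_cohort(simulation_config(noise_sd = 0.1, seed = 23))
  res <- suppressWarnings(analyze_cohort(co$trajectories,
                                         config = default_config()))
  h <- timing_histogram(res$events)
  modal <- h$bin_start_min[which.max(h$n_end)]
  expect_gte(modal, 60)
  expect_lte(modal, 180)
})

test_that("D'Agostino-Pearson omnibus matches an independent implementation", {
  # frozen from scipy.stats.normaltest on the same vectors
  r1 <- dagostino_pearson_test(sin(1:20))
  expect_equal(r1$statistic, 8.828599767037225, tolerance = 1e-10)
  expect_equal(r1$p, 0.012103024686599694, tolerance = 1e-10)
  r2 <- dagostino_pearson_test(exp(sin(1:30)))
  expect_equal(r2$statistic, 11.01081535536358, tolerance = 1e-10)
  expect_equal(r2$p, 0.004064731142883262, tolerance = 1e-10)
  expect_error(dagostino_pearson_test(1:7), "at least 8")
})

test_that("normality gate selects the test the data deserve", {
  set.seed(4020)
  a <- rnorm(100); b <- rnorm(100)
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$decision, "t")
  expect_true(all(cmp$tests$p > 0.05))

  set.seed(4025)
  e1 <- rexp(60); e2 <- rexp(60)
  cmpe <- compare_conditions(e1, e2)
  expect_equal(cmpe$decision, "mann_whitney")
  expect_equal(cmpe$tests$test, "Mann-Whitney U")

  expect_error(compare_conditions(c(1, 2), rnorm(10)), "at least 3")
  expect_warning(cmp0 <- compare_conditions(rep(2, 5), rep(2, 6)),
                 "degenerate")
  expect_equal(cmp0$tests$p, 1)
})

test_that("test selection is deterministic given the data", {
  set.seed(99)
  a <- rgamma(40, 2); b <- rgamma(40, 2)
  d1 <- compare_conditions(a, b)$decision
  d2 <- compare_conditions(a, b)$decision
  expect_identical(d1, d2)
})
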