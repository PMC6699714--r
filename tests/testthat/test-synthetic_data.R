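test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_control = 2, n_gradual = 2, n_instant = 2,
                           n_combined = 2, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$trajectories, `[[`, "lengths"),
                   lapply(b$trajectories, `[[`, "lengths"))
  expect_identical(a$truth, b$truth)
  # a different master seed changes realizations but not composition
  cfg2 <- cfg; cfg2$seed <- 43L
  c2 <- simulate_cohort(cfg2)
  expect_identical(names(c2$trajectories), names(a$trajectories))
  expect_false(identical(c2$trajectories[[1]]$lengths,
                         a$trajectories[[1]]$lengths))
})

test_that("controls realise the stated measurement process", {
  # no noise, no drift: constant series
  flat <- simulate_control(simulation_config(noise_sd = 0, drift = 0),
                           seed = 8)
  expect_equal(length(unique(flat$lengths)), 1)
  expect_equal(length(flat$times), 481)  # 12 h at 90 s
  # same seed twice: identical
  cfg <- simulation_config()
  expect_identical(simulate_control(cfg, seed = 3)$lengths,
                   simulate_control(cfg, seed = 3)$lengths)
  # calibrated noise gives consecutive-difference SD near 1.53 um
  cfgn <- simulation_config(noise_sd = 1.53 / sqrt(2), seed = 1)
  dsds <- vapply(1:6, function(i) {
    sd(diff(simulate_control(cfgn, seed = i)$lengths))
  }, numeric(1))
  expect_lt(abs(mean(dsds) - 1.53), 0.1)
})

test_that("noiseless event geometries honour their parameters", {
  # instant: flat at 4.5 um, one-frame drop -> minimum rate 3 um/min
  cfgi <- noiseless_config(drift = 0, max_length_mean = 4.5,
                           max_length_sd = 0, max_length_floor = 1)
  evi <- simulate_event("instant", cfgi, seed = 2)
  expect_equal(evi$truth$instant_min_rate_um_per_min, 3.0)
  expect_equal(evi$truth$start_index + 1L, evi$truth$completion_index)
  # the observable rate underestimates the true shedding rate
  expect_gte(evi$truth$true_shed_rate_um_per_min,
             evi$truth$instant_min_rate_um_per_min)

  # combined: gradual phase ends at fraction x max length
  cfgc <- noiseless_config(drift = 0, max_length_mean = 10,
                           max_length_sd = 0, max_length_floor = 1,
                           combined_instant_fraction = 0.726)
  evc <- simulate_event("combined", cfgc, seed = 3)
  expect_equal(evc$truth$penultimate_length_um, 7.26)
  expect_equal(evc$truth$fraction_instant, 0.726)
  tr <- evc$trajectory
  expect_equal(tr$lengths[evc$truth$completion_index - 1L], 7.26)

  # gradual at 0.016 um/min from 6.0 um takes 375 min to finish
  cfgg <- noiseless_config(drift = 0, max_length_mean = 6,
                           max_length_sd = 0, max_length_floor = 1,
                           gradual_rate_mean = 0.016, gradual_rate_sd = 0,
                           onset = "uniform", duration_min = 720)
  evg <- simulate_event("gradual", cfgg, seed = 4)
  elapsed <- evg$truth$end_time_min - evg$truth$start_time_min
  expect_equal(elapsed, 6 / 0.016, tolerance = 0.02)
  expect_equal(evg$truth$gradual_rate_um_per_min, 0.016, tolerance = 0.02)
})

test_that("cohorts have the requested composition", {
  co <- simulate_cohort(simulation_config(seed = 6))
  expect_length(co$trajectories, 79)
  expect_equal(nrow(co$truth), 69)
  expect_equal(unname(table(co$truth$class)[c("gradual", "instant",
                                              "combined")]),
               c(11L, 32L, 26L), ignore_attr = TRUE)
  expect_equal(sum(co$manifest$role == "control"), 10)
  one <- simulate_cohort(simulation_config(n_control = 0, n_gradual = 0,
                                           n_instant = 1, n_combined = 0))
  expect_equal(one$truth$class, "instant")
  expect_error(
    simulate_cohort(simulation_config(n_control = 0, n_gradual = 0,
                                      n_instant = 0, n_combined = 0)),
    "empty"
  )
})

test_that("generated rates span orders of magnitude", {
  co <- simulate_cohort(simulation_config(seed = 31))
  rates <- c(co$truth$gradual_rate_um_per_min,
             co$truth$instant_min_rate_um_per_min)
  rates <- rates[!is.na(rates)]
  expect_gte(log10(max(rates) / min(rates)), 2)
  expect_gte(max(rates), 1)    # instant rates reach um/min scale
  expect_lte(min(rates), 0.1)  # gradual rates sit at 1e-2 scale
})

test_that("cohort fixtures round-trip through the readers", {
  co <- simulate_cohort(simulation_config(n_control = 2, n_gradual = 1,
                                          n_instant = 1, n_combined = 1,
                                          noise_sd = 0.2, seed = 88))
  for (layout in c("long", "wide")) {
    dir <- withr::local_tempdir()
    write_cohort(co, dir, layout = layout)
    man <- read_manifest(file.path(dir, "manifest.csv"))
    back <- read_trajectories(file.path(dir, "trajectories.csv"), man,
                              layout = layout)
    expect_setequal(names(back), names(co$trajectories))
    for (id in names(back)) {
      expect_equal(back[[id]]$lengths, co$trajectories[[id]]$lengths,
                   tolerance = 1e-12)
      expect_equal(back[[id]]$role, co$trajectories[[id]]$role)
    }
  }
})
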