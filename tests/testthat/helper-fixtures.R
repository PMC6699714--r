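# Shared helpers: quick trajectory construction and tiny simulated cohorts.

make_traj <- function(lengths, dt = 90, id = "t1",
                      role = "experimental", condition = "test") {
  length_trajectory(id, times = (seq_along(lengths) - 1) * dt,
                    lengths = lengths, condition = condition, role = role,
                    frame_interval = dt)
}

# A baseline with the shipped literal constants, for tests that do not
# exercise calibration itself.
literal_baseline <- function() control_baseline()

# Noiseless generator configuration with deterministic kinetics.
noiseless_config <- function(...) {
  simulation_config(noise_sd = 0, ...)
}

# Match pipeline calls against ground truth; returns a data.frame with
# truth and called class per event.
call_vs_truth <- function(cohort, config = default_config()) {
  res <- analyze_cohort(cohort$trajectories, config = config)
  idx <- match(cohort$truth$cilium_id, res$events$cilium_id)
  data.frame(cilium_id = cohort$truth$cilium_id,
             truth = cohort$truth$class,
             called = res$events$class[idx],
             stringsAsFactors = FALSE)
}
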