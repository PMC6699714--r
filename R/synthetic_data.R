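#' Generative specification for synthetic cilium-loss cohorts
#'
#' Describes a cohort of synthetic trajectories with the statistical
#' structure the analysis assumes: 12-hour movies at a fixed frame
#' interval, additive Gaussian measurement noise on every length while the
#' cilium exists, a slow linear background drift, asynchronous event
#' onsets whose completion times peak at 1--3 h, and class-specific
#' kinetics (gradual linear resorption; single-frame shedding; resorption
#' followed by shedding). Defaults are the reported operating point of
#' the measurement process.
#'
#' @param n_control,n_gradual,n_instant,n_combined Cohort composition.
#' @param duration_min Movie duration in minutes (default 720 = 12 h).
#' @param frame_interval_s Seconds between frames (default 90).
#' @param max_length_mean,max_length_sd,max_length_floor Truncated-normal
#'   distribution of initial (maximum) cilium length, um.
#' @param gradual_rate_mean,gradual_rate_sd Natural-scale mean and SD of
#'   resorption rates for Gradual-only events, um/min.
#' @param combined_gradual_rate_mean,combined_gradual_rate_sd Same for
#'   the gradual phase of Combined events.
#' @param rate_floor Lower clip on drawn resorption rates, um/min
#'   (default 0.01, the bottom of the observed gradual range; it also
#'   keeps every drawn rate distinguishable from the background slope).
#' @param rate_dist `"lognormal"` (moment-matched to mean/SD; rates are
#'   positive and the SDs rival the means) or `"truncnormal"`.
#' @param instant_penultimate_floor Minimum length (um) from which a
#'   single-frame drop may occur (default 1.6, just above the 1.532 um
#'   instant threshold).
#' @param instant_penultimate_mean,instant_penultimate_sd If
#'   `instant_penultimate_mean` is set, Instant events draw their
#'   penultimate length from Normal(mean, sd) truncated below at
#'   `instant_penultimate_floor` instead of deriving it from the initial
#'   length and drift.
#' @param combined_instant_fraction Target fraction of the maximum length
#'   shed in the terminal frame of Combined events (default 0.726).
#' @param onset `"triangular"` (completion times over 0..duration with
#'   mode at `onset_mode_min`, so end points peak at 1--3 h) or
#'   `"uniform"`.
#' @param onset_mode_min Mode of the triangular completion-time
#'   distribution, minutes.
#' @param drift Background length drift applied to all trajectories,
#'   um/min (default -0.005).
#' @param noise_sd Per-measurement Gaussian noise SD, um. Default
#'   1.53/sqrt(2), which makes the SD of consecutive differences match
#'   the 1.53 um calibration.
#' @param condition Condition label stamped on the trajectories.
#' @param seed Master seed; given (config, seed) the output is
#'   bit-reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_control = 10L, n_gradual = 11L,
                              n_instant = 32L, n_combined = 26L,
                              duration_min = 720, frame_interval_s = 90,
                              max_length_mean = 5, max_length_sd = 1.5,
                              max_length_floor = 2,
                              gradual_rate_mean = 0.08,
                              gradual_rate_sd = 0.11,
                              combined_gradual_rate_mean = 0.08,
                              combined_gradual_rate_sd = 0.26,
                              rate_floor = 0.01,
                              rate_dist = c("lognormal", "truncnormal"),
                              instant_penultimate_floor = 1.6,
                              instant_penultimate_mean = NULL,
                              instant_penultimate_sd = 1.0,
                              combined_instant_fraction = 0.726,
                              onset = c("triangular", "uniform"),
                              onset_mode_min = 120,
                              drift = -0.005,
                              noise_sd = 1.53 / sqrt(2),
                              condition = "synthetic",
                              seed = 1L) {
  rate_dist <- match.arg(rate_dist)
  onset <- match.arg(onset)
  cfg <- list(
    n_control = as.integer(n_control), n_gradual = as.integer(n_gradual),
    n_instant = as.integer(n_instant), n_combined = as.integer(n_combined),
    duration_min = duration_min, frame_interval_s = frame_interval_s,
    max_length_mean = max_length_mean, max_length_sd = max_length_sd,
    max_length_floor = max_length_floor,
    gradual_rate_mean = gradual_rate_mean,
    gradual_rate_sd = gradual_rate_sd,
    combined_gradual_rate_mean = combined_gradual_rate_mean,
    combined_gradual_rate_sd = combined_gradual_rate_sd,
    rate_floor = rate_floor, rate_dist = rate_dist,
    instant_penultimate_floor = instant_penultimate_floor,
    instant_penultimate_mean = instant_penultimate_mean,
    instant_penultimate_sd = instant_penultimate_sd,
    combined_instant_fraction = combined_instant_fraction,
    onset = onset, onset_mode_min = onset_mode_min,
    drift = drift, noise_sd = noise_sd,
    condition = condition, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(noise_sd >= 0, max_length_sd >= 0, gradual_rate_sd >= 0,
              combined_gradual_rate_sd >= 0, max_length_floor > 0,
              instant_penultimate_floor > 0, rate_floor > 0,
              duration_min > 0, frame_interval_s > 0)
    if (combined_instant_fraction <= 0 || combined_instant_fraction >= 1) {
      stop("combined_instant_fraction must lie strictly in (0, 1)")
    }
  })
  structure(cfg, class = "simulation_config")
}

## Coerce a plain list (e.g. the `sim` section of a config file) to a
## validated simulation_config.
as_simulation_config <- function(x) {
  if (inherits(x, "simulation_config")) return(x)
  do.call(simulation_config, x[!vapply(x, is.null, logical(1))])
}

time_grid <- function(cfg) {
  seq(0, cfg$duration_min * 60, by = cfg$frame_interval_s)
}

## Normal truncated below at `floor`, by inverse-CDF sampling.
rtrunc_normal <- function(n, mean, sd, floor) {
  if (sd == 0) {
    if (mean < floor) stop("degenerate truncated normal: mean below floor")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(floor, mean, sd)
  if (plo > 1 - 1e-12) {
    stop("truncated normal has no mass above its floor")
  }
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

## Resorption-rate draw: log-normal moment-matched to (mean, sd) on the
## natural scale, clipped below at the rate floor; truncated normal
## selectable.
draw_rate <- function(n, mean, sd, cfg) {
  if (sd == 0) return(rep(max(mean, cfg$rate_floor), n))
  r <- if (cfg$rate_dist == "lognormal") {
    sdlog2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2,
                  sdlog = sqrt(sdlog2))
  } else {
    rtrunc_normal(n, mean, sd, cfg$rate_floor)
  }
  pmax(r, cfg$rate_floor)
}

## Event completion time (minutes). Triangular over (0, duration) with the
## configured mode puts most completions at 1-3 h.
draw_end_time <- function(cfg) {
  if (cfg$onset == "uniform") {
    return(stats::runif(1, 0, cfg$duration_min))
  }
  a <- 0
  b <- cfg$duration_min
  m <- cfg$onset_mode_min
  u <- stats::runif(1)
  fc <- (m - a) / (b - a)
  if (u < fc) a + sqrt(u * (b - a) * (m - a))
  else b - sqrt((1 - u) * (b - a) * (b - m))
}

## Snap an end time to the frame grid, keeping at least `min_frames`
## frames before completion and staying inside the movie.
snap_completion <- function(t_end_min, cfg, n, min_frames = 5L) {
  c_idx <- round(t_end_min * 60 / cfg$frame_interval_s) + 1L
  max(min(c_idx, n), min_frames)
}

#' Simulate a non-disassembling control trajectory
#'
#' Length is a constant plus linear background drift plus i.i.d. Gaussian
#' measurement noise, clipped at zero: the stochastic fluctuation of a
#' cilium that is tracked but never lost.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (default: the config's master seed).
#' @param cilium_id Identifier for the trajectory.
#' @return A [length_trajectory()] with role `"control"`.
#' @export
simulate_control <- function(config, seed = config$seed,
                             cilium_id = "control") {
  config <- as_simulation_config(config)
  set.seed(seed)
  times <- time_grid(config)
  tmin <- times / 60
  # controls are non-disassembling by definition: the initial length is
  # drawn so the noiseless track stays positive over the whole movie
  survive_floor <- max(config$max_length_floor,
                       abs(min(config$drift, 0)) * config$duration_min +
                         0.25)
  l0 <- tryCatch(
    rtrunc_normal(1, config$max_length_mean, config$max_length_sd,
                  survive_floor),
    error = function(e) rtrunc_normal(1, config$max_length_mean,
                                      config$max_length_sd,
                                      config$max_length_floor)
  )
  signal <- l0 + config$drift * tmin
  if (min(signal) < 0) {
    warning("drift drives the noiseless control ", cilium_id,
            " to zero length within the movie", call. = FALSE)
  }
  obs <- signal
  if (config$noise_sd > 0) {
    obs <- obs + stats::rnorm(length(obs), 0, config$noise_sd)
  }
  length_trajectory(cilium_id, times, pmax(obs, 0),
                    condition = config$condition, role = "control",
                    frame_interval = config$frame_interval_s)
}

#' Simulate one cilium-loss event with known ground truth
#'
#' Builds a noiseless piecewise-linear length signal for the requested
#' class, superposes background drift and measurement noise on every frame
#' at which the cilium still exists, and records zero afterwards (an
#' absent cilium has no length to mis-measure). The returned ground truth
#' carries the true class, start and completion frames, phase rates, and —
#' for classes with a shedding step — the true shedding rate, drawn as the
#' penultimate length over a shedding duration uniform between 5 s and one
#' frame interval, so the observable single-frame rate is always a lower
#' bound on it.
#'
#' Class geometries (noiseless):
#' \itemize{
#'   \item gradual — baseline, then linear decline from the detected-start
#'     level to zero at the completion frame;
#'   \item instant — baseline until the penultimate frame, then a
#'     single-frame drop to zero from a length above
#'     `instant_penultimate_floor`;
#'   \item combined — baseline, linear decline to
#'     `combined_instant_fraction * max length`, then a single-frame drop
#'     to zero.
#' }
#' Draws that cannot realise the geometry (e.g. a penultimate length at or
#' below the floor, or background drift alone reaching the target level)
#' are rejected and redrawn; persistent impossibility is an error.
#'
#' @param class `"gradual"`, `"instant"` or `"combined"`.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param cilium_id Identifier.
#' @return List with `trajectory` (a [length_trajectory()], role
#'   `"experimental"`) and `truth` (one-row data frame).
#' @export
simulate_event <- function(class = c("gradual", "instant", "combined"),
                           config, seed = config$seed,
                           cilium_id = class) {
  class <- match.arg(class)
  config <- as_simulation_config(config)
  set.seed(seed)
  times <- time_grid(config)
  tmin <- times / 60
  n <- length(times)
  dt_min <- config$frame_interval_s / 60

  geom <- switch(class,
    instant = draw_instant_geometry(config, tmin, n),
    combined = draw_combined_geometry(config, tmin, n),
    gradual = draw_gradual_geometry(config, tmin, n)
  )
  signal <- geom$signal
  c_idx <- geom$completion

  obs <- numeric(n)
  alive <- seq_len(c_idx - 1L)
  obs[alive] <- signal[alive]
  if (config$noise_sd > 0) {
    obs[alive] <- pmax(obs[alive] +
                         stats::rnorm(length(alive), 0, config$noise_sd), 0)
  }

  shed_s <- NA_real_
  true_shed_rate <- NA_real_
  if (class %in% c("instant", "combined")) {
    shed_s <- stats::runif(1, 5, config$frame_interval_s)
    true_shed_rate <- geom$l_pen / (shed_s / 60)
  }

  traj <- length_trajectory(cilium_id, times, obs,
                            condition = config$condition,
                            role = "experimental",
                            frame_interval = config$frame_interval_s)
  truth <- data.frame(
    cilium_id = cilium_id, class = class,
    start_index = geom$start, completion_index = c_idx,
    start_time_min = tmin[geom$start], end_time_min = tmin[c_idx],
    max_length_um = geom$l0, penultimate_length_um = geom$l_pen,
    gradual_rate_um_per_min = geom$gradual_rate,
    instant_min_rate_um_per_min =
      if (class == "gradual") NA_real_ else geom$l_pen / dt_min,
    true_shed_rate_um_per_min = true_shed_rate,
    shed_duration_s = shed_s,
    fraction_instant =
      if (class == "gradual") NA_real_ else geom$l_pen / geom$l0,
    stringsAsFactors = FALSE
  )
  list(trajectory = traj, truth = truth)
}

draw_instant_geometry <- function(cfg, tmin, n, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    c_idx <- snap_completion(draw_end_time(cfg), cfg, n)
    t_pen <- tmin[c_idx - 1L]
    if (!is.null(cfg$instant_penultimate_mean)) {
      l_pen <- rtrunc_normal(1, cfg$instant_penultimate_mean,
                             cfg$instant_penultimate_sd,
                             cfg$instant_penultimate_floor)
      l0 <- l_pen - cfg$drift * t_pen
    } else {
      l0 <- rtrunc_normal(1, cfg$max_length_mean, cfg$max_length_sd,
                          cfg$max_length_floor)
      l_pen <- l0 + cfg$drift * t_pen
      if (l_pen <= cfg$instant_penultimate_floor) next
    }
    signal <- pmax(l0 + cfg$drift * tmin, 0)
    signal[c_idx:n] <- 0
    return(list(signal = signal, completion = c_idx,
                start = c_idx - 1L, l0 = l0, l_pen = l_pen,
                gradual_rate = NA_real_))
  }
  stop("cannot realise an instant event: penultimate length never ",
       "exceeds the floor under this configuration")
}

draw_combined_geometry <- function(cfg, tmin, n, max_tries = 1000L) {
  frac <- cfg$combined_instant_fraction
  for (try in seq_len(max_tries)) {
    c_idx <- snap_completion(draw_end_time(cfg), cfg, n)
    t_pen <- tmin[c_idx - 1L]
    l0 <- rtrunc_normal(1, cfg$max_length_mean, cfg$max_length_sd,
                        cfg$max_length_floor)
    l_pen <- frac * l0
    # the gradual phase must lose something beyond background drift, and
    # the shed length must sit above the floor
    if (l_pen <= cfg$instant_penultimate_floor) next
    if (l0 + cfg$drift * t_pen <= l_pen) next
    r <- draw_rate(1, cfg$combined_gradual_rate_mean,
                   cfg$combined_gradual_rate_sd, cfg)
    t_start <- (l_pen - l0 + r * t_pen) / (r + cfg$drift)
    s_idx <- max(min(round(t_start * 60 / cfg$frame_interval_s) + 1L,
                     c_idx - 2L), 1L)
    t_s <- tmin[s_idx]
    l_s <- l0 + cfg$drift * t_s
    r_true <- (l_s - l_pen) / (t_pen - t_s)
    signal <- l0 + cfg$drift * tmin
    phase <- tmin >= t_s & tmin <= t_pen
    signal[phase] <- l_s - r_true * (tmin[phase] - t_s)
    signal <- pmax(signal, 0)
    signal[c_idx:n] <- 0
    return(list(signal = signal, completion = c_idx, start = s_idx,
                l0 = l0, l_pen = l_pen, gradual_rate = r_true))
  }
  stop("cannot realise a combined event: the configured fraction and ",
       "floors are incompatible")
}

draw_gradual_geometry <- function(cfg, tmin, n, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    c_idx <- snap_completion(draw_end_time(cfg), cfg, n)
    t_c <- tmin[c_idx]
    l0 <- rtrunc_normal(1, cfg$max_length_mean, cfg$max_length_sd,
                        cfg$max_length_floor)
    # the decline must outrun background drift
    if (l0 + cfg$drift * t_c <= 0) next
    r <- draw_rate(1, cfg$gradual_rate_mean, cfg$gradual_rate_sd, cfg)
    t_start <- (r * t_c - l0) / (r + cfg$drift)
    s_idx <- max(min(round(t_start * 60 / cfg$frame_interval_s) + 1L,
                     c_idx - 2L), 1L)
    t_s <- tmin[s_idx]
    l_s <- l0 + cfg$drift * t_s
    r_true <- l_s / (t_c - t_s)
    signal <- l0 + cfg$drift * tmin
    phase <- tmin >= t_s
    signal[phase] <- l_s - r_true * (tmin[phase] - t_s)
    signal <- pmax(signal, 0)
    signal[c_idx:n] <- 0
    return(list(signal = signal, completion = c_idx, start = s_idx,
                l0 = l0, l_pen = signal[c_idx - 1L],
                gradual_rate = r_true))
  }
  stop("cannot realise a gradual event under this configuration")
}

#' Simulate a labelled cohort of control and loss trajectories
#'
#' Draws one sub-seed per trajectory from the master seed, simulates the
#' configured number of controls and of events of each class, and emits a
#' manifest alongside the ground truth. Given (config, seed) the output
#' is bit-reproducible; changing only the master seed changes every noise
#' realisation but not the composition.
#'
#' @param config A [simulation_config()].
#' @return List with `trajectories` (named list), `truth` (data frame,
#'   one row per event, controls excluded), `manifest` (data frame) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  config <- as_simulation_config(config)
  counts <- c(control = config$n_control, gradual = config$n_gradual,
              instant = config$n_instant, combined = config$n_combined)
  if (sum(counts) == 0) {
    stop("cohort is empty: all class counts are zero")
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, sum(counts))
  prefix <- c(control = "ctrl", gradual = "grad", instant = "inst",
              combined = "comb")
  trajectories <- list()
  truth <- list()
  k <- 0L
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      k <- k + 1L
      id <- sprintf("%s_%03d", prefix[[cls]], i)
      if (cls == "control") {
        trajectories[[id]] <- simulate_control(config, seed = seeds[k],
                                               cilium_id = id)
      } else {
        ev <- simulate_event(cls, config, seed = seeds[k], cilium_id = id)
        trajectories[[id]] <- ev$trajectory
        truth[[id]] <- ev$truth
      }
    }
  }
  truth <- if (length(truth)) {
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  manifest <- data.frame(
    cilium_id = names(trajectories),
    condition = config$condition,
    role = vapply(trajectories, function(x) x$role, character(1)),
    source = "trajectories.csv",
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(trajectories = trajectories, truth = truth, manifest = manifest,
       config = config)
}

#' Write a simulated cohort as a fixture directory
#'
#' Writes `trajectories.csv` (long or wide layout), `manifest.csv`,
#' `truth.csv` and the generating configuration (`sim_config.yaml`, for
#' provenance) into `dir`. The trajectory file re-reads exactly through
#' [read_trajectories()].
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param layout `"long"` or `"wide"`.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    trajectories = file.path(dir, "trajectories.csv"),
    manifest = file.path(dir, "manifest.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "sim_config.yaml")
  )
  if (layout == "long") {
    long <- do.call(rbind, lapply(cohort$trajectories, function(tr) {
      data.frame(cilium_id = tr$cilium_id, time_s = tr$times,
                 length_um = tr$lengths, stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, paths$trajectories, row.names = FALSE)
  } else {
    cols <- list()
    nmax <- max(vapply(cohort$trajectories, n_points, integer(1)))
    for (tr in cohort$trajectories) {
      pad <- rep(NA_real_, nmax - n_points(tr))
      cols[[paste0(tr$cilium_id, "_time_s")]] <- c(tr$times, pad)
      cols[[paste0(tr$cilium_id, "_length_um")]] <- c(tr$lengths, pad)
    }
    utils::write.csv(as.data.frame(cols, check.names = FALSE),
                     paths$trajectories, row.names = FALSE)
  }
  utils::write.csv(cohort$manifest, paths$manifest, row.names = FALSE)
  utils::write.csv(cohort$truth, paths$truth, row.names = FALSE)
  yaml::write_yaml(unclass(cohort$config), paths$config)
  invisible(paths)
}
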