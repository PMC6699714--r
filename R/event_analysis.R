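#' Detect the completion point of a loss event
#'
#' The completion point is the first time point at which the observed
#' length is at or below `zero_tol` and stays there for the rest of the
#' movie — a transient dip to zero followed by recovery is measurement
#' noise, not loss. Detection runs on the observed (raw) lengths:
#' symmetric smoothing mixes post-event zeros into the last frames of the
#' cilium's life and would displace the terminus.
#'
#' @param traj A `cilium_trajectory` (a `smoothed_trajectory` is accepted;
#'   its raw parent lengths are used).
#' @param zero_tol Length (um) at or below which the cilium counts as
#'   absent. Default 0; raise it if a fluorescence background floor keeps
#'   recorded lengths slightly positive.
#' @return Completion index (1-based), or `NA_integer_` if the trajectory
#'   is censored (never reaches zero).
#' @export
detect_completion <- function(traj, zero_tol = 0) {
  x <- traj$lengths
  below <- x <= zero_tol
  # last index before which some point is above tolerance
  ok <- rev(cumprod(rev(below))) == 1
  if (!any(ok)) {
    return(NA_integer_)
  }
  which(ok)[1]
}

#' Detect the start point of a loss event
#'
#' Scans backwards from the completion point until the length derivative
#' is no different in magnitude from the mean background slope of control
#' cilia: walking interval index `i` from `completion - 1` down to 1, the
#' scan stops at the first `i` with
#' `|derivative(i)| <= slope_tol_factor * |mean_slope| + noise_k * diff_sd / dt`
#' (with `dt` the interval length in minutes), and the start index is
#' `i + 1`. If the scan exhausts the trajectory the event started before
#' imaging began and the start index is 1.
#'
#' With `window > 1` the derivatives of the pre-drop intervals are
#' smoothed with a truncated, renormalized moving kernel before the
#' comparison. Smoothing is applied to the derivative sequence rather
#' than the length series: the two are equivalent away from the segment
#' ends, but averaging derivatives leaves a constant slope exactly
#' invariant under the edge-truncated kernel, whereas averaging lengths
#' shrinks the edge derivative and would misread slow resorption next to
#' the terminal drop. The final (drop) interval always keeps its raw
#' derivative, so a single-frame loss is never blurred away.
#'
#' With the default `noise_k = 0` the stopping rule is the literal
#' comparison against the background slope, which is exact on noiseless
#' data. A positive `noise_k` widens the band by `noise_k` standard
#' deviations of the consecutive-difference noise calibrated from
#' controls.
#'
#' @param traj A `cilium_trajectory` covering indices 1..completion (raw
#'   lengths are used; a `smoothed_trajectory` contributes its smoothed
#'   values only when `window = 1`).
#' @param completion Completion index from [detect_completion()].
#' @param baseline A [control_baseline()].
#' @param slope_tol_factor Multiplier on `|mean_slope|` (default 1).
#' @param noise_k Width of the optional noise band (default 0 = off).
#' @param window Odd derivative-smoothing window in frames (default 1 =
#'   no smoothing).
#' @param kernel Kernel for the derivative smoothing.
#' @return Start index (1-based), between 1 and `completion - 1`; it
#'   equals `completion - 1` when only the final interval shows loss.
#' @export
detect_start <- function(traj, completion, baseline,
                         slope_tol_factor = 1, noise_k = 0,
                         window = 1L, kernel = "gaussian") {
  if (is.na(completion)) {
    stop("cannot detect a start point on a censored trajectory")
  }
  if (completion <= 1) {
    stop("completion at the first point: no pre-event data (",
         traj$cilium_id, ")")
  }
  x <- smoothed_values(traj)
  dt_min <- diff(traj$times) / 60
  d <- (x[-1] - x[-length(x)]) / dt_min
  n_pre <- completion - 2L  # intervals strictly before the drop interval
  if (window > 1L && n_pre >= 2L) {
    d[seq_len(n_pre)] <- smooth_series(d[seq_len(n_pre)],
                                       min(window, n_pre), kernel)
  }
  band0 <- slope_tol_factor * abs(baseline$mean_slope)
  dsd <- if (is.na(baseline$diff_sd)) 0 else baseline$diff_sd
  for (i in seq(completion - 1, 1)) {
    tol <- band0 + noise_k * dsd / dt_min[i]
    if (abs(d[i]) <= tol + 1e-9) {
      # the final interval itself showing no decline means the event is,
      # at the latest, at the penultimate point
      return(min(i + 1L, completion - 1L))
    }
  }
  1L
}

## Truncated-kernel renormalized moving average of a plain numeric
## series (shared by length smoothing and derivative smoothing).
smooth_series <- function(x, window, kernel) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window - 1L
  if (window <= 1L) return(x)
  n <- length(x)
  w <- smoothing_kernel(window, kernel)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    wi <- w[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(wi * x[lo:hi]) / sum(wi)
  }
  out
}

#' Classify a loss event as Gradual, Instant or Combined
#'
#' Applies the three-way rule driven by the detected start point and the
#' length at the penultimate time point (the last frame at which the
#' cilium exists):
#' \itemize{
#'   \item Instant — the start point is the penultimate point (all loss in
#'     one frame) and the penultimate length exceeds the instant
#'     threshold;
#'   \item Combined — the start precedes the penultimate point and the
#'     penultimate length exceeds the threshold (a gradual phase followed
#'     by a single-frame loss);
#'   \item Gradual — the start precedes the penultimate point and the
#'     penultimate length is at or below the threshold (the final drop is
#'     indistinguishable from measurement error).
#' }
#' The degenerate case (single-frame loss from below the threshold) is by
#' the same logic indistinguishable from noise riding on resorption and is
#' assigned the `degenerate_policy` class (default `"gradual"`) with a
#' flag.
#'
#' @param start Start index from [detect_start()].
#' @param completion Completion index from [detect_completion()].
#' @param penultimate_length Observed length (um) at `completion - 1`.
#' @param instant_threshold Threshold length, um (see
#'   [control_baseline()]).
#' @param degenerate_policy Class for the degenerate case.
#' @return A list with `class` (`"gradual"`, `"instant"` or `"combined"`)
#'   and `degenerate` (logical).
#' @export
classify_event <- function(start, completion, penultimate_length,
                           instant_threshold,
                           degenerate_policy = "gradual") {
  penult <- completion - 1L
  stopifnot(start <= penult)
  above <- penultimate_length > instant_threshold
  if (start < penult && above) {
    list(class = "combined", degenerate = FALSE)
  } else if (start == penult && above) {
    list(class = "instant", degenerate = FALSE)
  } else if (start < penult) {
    list(class = "gradual", degenerate = FALSE)
  } else {
    list(class = degenerate_policy, degenerate = TRUE)
  }
}

#' Compute per-phase metrics of a classified loss event
#'
#' Rates are amplitudes over elapsed time measured on the observed (raw)
#' lengths at the detected indices, in um/min. The gradual rate spans the
#' start to the penultimate point (gradual and combined events); the
#' instant minimum rate is the penultimate length divided by the final
#' frame interval (instant and combined events) — a lower bound, since the
#' loss completes at some unobserved moment within that frame. Fractions
#' are of the cilium's maximum length: `fraction_instant` is the portion
#' shed in the terminal frame, `fraction_gradual` the portion resorbed
#' between start and penultimate point.
#'
#' @param traj The original [length_trajectory()] (raw lengths).
#' @param start,completion Detected indices.
#' @param event_class Classification from [classify_event()].
#' @param max_length Maximum length used for the fractions; defaults to
#'   the trajectory's raw maximum. [analyze_trajectory()] passes the
#'   maximum of the smoothed series so a single noisy spike cannot deflate
#'   the fractions.
#' @param degenerate Logical flag from [classify_event()].
#' @return One-row data frame with the event's metrics (columns as in
#'   [write_events_table()] plus `start_index`, `completion_index`).
#' @export
compute_event_metrics <- function(traj, start, completion, event_class,
                                  max_length = NULL, degenerate = FALSE) {
  penult <- completion - 1L
  x <- traj$lengths
  tmin <- traj$times / 60
  if (is.null(max_length)) {
    max_length <- max(x[seq_len(penult)])
  }
  if (max_length <= 0) {
    stop("maximum length is zero for ", traj$cilium_id)
  }
  l_start <- x[start]
  l_pen <- x[penult]

  gradual_rate <- NA_real_
  fraction_gradual <- NA_real_
  if (event_class %in% c("gradual", "combined") && !degenerate) {
    dt <- tmin[penult] - tmin[start]
    if (dt <= 0) {
      stop("zero elapsed time in the gradual phase of ", traj$cilium_id)
    }
    gradual_rate <- (l_start - l_pen) / dt
    fraction_gradual <- (l_start - l_pen) / max_length
  }

  instant_rate <- NA_real_
  fraction_instant <- NA_real_
  if (event_class %in% c("instant", "combined")) {
    dt <- tmin[completion] - tmin[penult]
    if (dt <= 0) {
      stop("zero elapsed time in the instant phase of ", traj$cilium_id)
    }
    instant_rate <- l_pen / dt
    fraction_instant <- min(l_pen / max_length, 1)
  }
  if (!is.na(fraction_gradual)) {
    ceiling_g <- 1 - ifelse(is.na(fraction_instant), 0, fraction_instant)
    fraction_gradual <- min(max(fraction_gradual, 0), ceiling_g)
  }

  data.frame(
    cilium_id = traj$cilium_id,
    condition = traj$condition,
    class = event_class,
    start_index = start,
    completion_index = completion,
    start_time_min = tmin[start],
    end_time_min = tmin[completion],
    start_length_um = l_start,
    penultimate_length_um = l_pen,
    max_length_um = max_length,
    gradual_rate_um_per_min = gradual_rate,
    instant_min_rate_um_per_min = instant_rate,
    fraction_gradual = fraction_gradual,
    fraction_instant = fraction_instant,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

censored_row <- function(traj) {
  data.frame(
    cilium_id = traj$cilium_id, condition = traj$condition,
    class = "censored", start_index = NA_integer_,
    completion_index = NA_integer_, start_time_min = NA_real_,
    end_time_min = NA_real_, start_length_um = NA_real_,
    penultimate_length_um = NA_real_, max_length_um = NA_real_,
    gradual_rate_um_per_min = NA_real_,
    instant_min_rate_um_per_min = NA_real_,
    fraction_gradual = NA_real_, fraction_instant = NA_real_,
    degenerate = FALSE, stringsAsFactors = FALSE
  )
}

#' Detect, classify and measure the loss event of one trajectory
#'
#' Runs the full per-cilium pipeline: completion detection on the observed
#' lengths; backward start-point scan against the control baseline, with
#' the pre-drop derivatives smoothed by the configured kernel (the kernel
#' never straddles the terminal drop, which would smear a single-frame
#' loss into an apparent gradual one); classification on the observed
#' penultimate length; metric computation on raw lengths, with the
#' fraction denominator taken from the smoothed pre-drop maximum. A
#' trajectory that never reaches zero, or whose very first point is
#' already zero, is returned as censored.
#'
#' @param traj A [length_trajectory()].
#' @param baseline A [control_baseline()].
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @return One-row events data frame (see [compute_event_metrics()]).
#' @export
analyze_trajectory <- function(traj, baseline, config = default_config()) {
  comp <- detect_completion(traj, zero_tol = config$event$zero_tol)
  if (is.na(comp)) {
    return(censored_row(traj))
  }
  if (comp <= 1) {
    warning("trajectory ", traj$cilium_id,
            " is already at zero length at the first frame; censored",
            call. = FALSE)
    return(censored_row(traj))
  }
  n_alive <- comp - 1L
  window <- min(config$smoothing$window, n_alive)
  if (window %% 2L == 0L) window <- window - 1L
  alive <- truncate_trajectory(traj, n_alive)
  sm <- smooth_trajectory(alive, window = window,
                          kernel = config$smoothing$kernel)

  start <- detect_start(truncate_trajectory(traj, comp), comp, baseline,
                        slope_tol_factor = config$event$slope_tol_factor,
                        noise_k = config$event$noise_k,
                        window = window,
                        kernel = config$smoothing$kernel)
  cls <- classify_event(start, comp, traj$lengths[comp - 1L],
                        instant_threshold = baseline$instant_threshold,
                        degenerate_policy = config$event$degenerate_policy)
  compute_event_metrics(traj, start, comp, cls$class,
                        max_length = max(sm$smoothed),
                        degenerate = cls$degenerate)
}

#' Analyse a cohort of trajectories
#'
#' Calibrates the control baseline from the cohort's control trajectories
#' (unless one is supplied) and classifies every experimental trajectory.
#' Without controls, the baseline overrides in `config$baseline` must be
#' set; the shipped literal constants then fill any field left `NULL`.
#'
#' @param trajectories List of [length_trajectory()] objects (mixed roles
#'   allowed).
#' @param baseline Optional precomputed [control_baseline()].
#' @param config Configuration list.
#' @return A list with `events` (data frame, one row per experimental
#'   trajectory, censored included) and `baseline`.
#' @export
analyze_cohort <- function(trajectories, baseline = NULL,
                           config = default_config()) {
  roles <- vapply(trajectories, function(x) x$role, character(1))
  controls <- trajectories[roles == "control"]
  experimental <- trajectories[roles == "experimental"]
  if (is.null(baseline)) {
    ov_thr <- config$baseline$instant_threshold_override
    ov_slope <- config$baseline$mean_slope_override
    if (length(controls)) {
      baseline <- estimate_baseline(controls,
                                    instant_threshold = ov_thr,
                                    mean_slope_override = ov_slope)
    } else if (!is.null(ov_thr) || !is.null(ov_slope)) {
      baseline <- control_baseline(
        mean_slope = if (is.null(ov_slope)) .default_mean_slope else ov_slope,
        instant_threshold = if (is.null(ov_thr)) .default_instant_threshold
                            else ov_thr
      )
    } else {
      stop("baseline requirement: no control trajectories in the cohort ",
           "and no baseline override configured")
    }
  }
  rows <- lapply(experimental, analyze_trajectory, baseline = baseline,
                 config = config)
  events <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(events)) {
    events <- censored_row(length_trajectory("x", c(0, 1, 2),
                                             c(1, 1, 1)))[0, ]
  }
  list(events = events, baseline = baseline)
}
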