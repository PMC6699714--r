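#' Smooth a length trajectory with a moving weighted average
#'
#' Applies a Gaussian-weighted (default) or uniform moving average of odd
#' width `window` to the length series. At the edges the kernel is
#' truncated to the available points and renormalized to sum to one — no
#' padding values are invented. Output is clipped at zero. `window = 1`
#' returns the input unchanged.
#'
#' The Gaussian kernel has standard deviation `window/4` frames, so the
#' window spans two standard deviations on each side.
#'
#' @param traj A [length_trajectory()].
#' @param window Odd positive integer, at most the trajectory length.
#' @param kernel `"gaussian"` or `"uniform"`.
#' @return A `smoothed_trajectory`: the parent trajectory with an added
#'   `smoothed` field (same cardinality as `times`) and smoothing metadata.
#' @examples
#' tr <- length_trajectory("c1", c(0, 90, 180), c(5, 4, 3))
#' smooth_trajectory(tr, window = 3, kernel = "uniform")$smoothed
#' @export
smooth_trajectory <- function(traj, window = 5L,
                              kernel = c("gaussian", "uniform")) {
  kernel <- match.arg(kernel)
  window <- as.integer(window)
  n <- n_points(traj)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer, got ", window)
  }
  if (window > n) {
    stop("window (", window, ") exceeds trajectory length (", n, ")")
  }
  out <- traj
  out$smoothed <- pmax(smooth_series(traj$lengths, window, kernel), 0)
  out$window <- window
  out$kernel <- kernel
  class(out) <- c("smoothed_trajectory", "cilium_trajectory")
  out
}

#' Smoothing kernel weights
#'
#' @param window Odd positive integer width in frames.
#' @param kernel `"gaussian"` (sd = window/4 frames) or `"uniform"`.
#' @return Numeric vector of `window` weights summing to 1.
#' @export
smoothing_kernel <- function(window, kernel = c("gaussian", "uniform")) {
  kernel <- match.arg(kernel)
  half <- (window - 1L) %/% 2L
  w <- if (kernel == "uniform") {
    rep(1, window)
  } else {
    sigma <- window / 4
    exp(-((-half:half)^2) / (2 * sigma^2))
  }
  w / sum(w)
}

smoothed_values <- function(traj) {
  if (!is.null(traj$smoothed)) traj$smoothed else traj$lengths
}

#' Length derivative at an interval
#'
#' The derivative between consecutive time points, attributed to the left
#' point: `(length[i+1] - length[i]) / dt`, with `dt` the actual elapsed
#' time converted to minutes. On a smoothed trajectory the smoothed values
#' are used.
#'
#' @param traj A `cilium_trajectory` or `smoothed_trajectory`.
#' @param i Interval index, `1 <= i < n` (1-based).
#' @return Rate in um/min.
#' @export
derivative_at <- function(traj, i) {
  n <- n_points(traj)
  if (i < 1 || i >= n) {
    stop("interval index out of range: ", i, " (trajectory has ", n,
         " points)")
  }
  x <- smoothed_values(traj)
  (x[i + 1] - x[i]) / ((traj$times[i + 1] - traj$times[i]) / 60)
}

#' All interval derivatives of a trajectory
#'
#' @param traj A `cilium_trajectory` or `smoothed_trajectory`.
#' @return Numeric vector of `n - 1` rates in um/min; element `i` is the
#'   derivative attributed to point `i`.
#' @export
trajectory_derivatives <- function(traj) {
  x <- smoothed_values(traj)
  diff(x) / (diff(traj$times) / 60)
}

#' Construct a control baseline by hand
#'
#' Bundles the calibration constants the event detector needs: the mean
#' background slope of non-disassembling control cilia and the dispersion
#' of consecutive length differences that serves as a measurement-error
#' proxy. Used directly when no control trajectories are available; the
#' shipped defaults are the literature constants (-0.005 um/min and
#' 1.532 um).
#'
#' @param mean_slope Mean per-cilium least-squares slope, um/min (signed).
#' @param diff_sd Mean over control cilia of the per-cilium SD of
#'   consecutive length differences, um.
#' @param max_diff_sd Maximum over control cilia of that SD, um.
#' @param instant_threshold Length (um) above which a single-frame
#'   disappearance is called Instant rather than measurement noise.
#' @param n_controls Number of control cilia behind the estimates.
#' @return A `control_baseline` object.
#' @export
control_baseline <- function(mean_slope = .default_mean_slope,
                             diff_sd = NA_real_,
                             max_diff_sd = NA_real_,
                             instant_threshold = .default_instant_threshold,
                             n_controls = 0L) {
  if (!is.na(diff_sd) && diff_sd < 0) stop("diff_sd must be >= 0")
  if (!is.na(diff_sd) && !is.na(max_diff_sd) && max_diff_sd < diff_sd) {
    stop("max_diff_sd must be >= diff_sd")
  }
  if (instant_threshold <= 0) stop("instant_threshold must be positive")
  structure(
    list(mean_slope = mean_slope, diff_sd = diff_sd,
         max_diff_sd = max_diff_sd, instant_threshold = instant_threshold,
         n_controls = as.integer(n_controls)),
    class = "control_baseline"
  )
}

#' @export
print.control_baseline <- function(x, ...) {
  cat(sprintf(
    paste0("<control_baseline> mean slope %.4g um/min, diff SD %.4g um ",
           "(max %.4g), instant threshold %.4g um, n = %d\n"),
    x$mean_slope, x$diff_sd, x$max_diff_sd, x$instant_threshold,
    x$n_controls
  ))
  invisible(x)
}

#' Calibrate the control baseline from non-disassembling cilia
#'
#' For each control trajectory the raw (unsmoothed) lengths are used to
#' compute (i) the least-squares slope of length versus time, in um/min,
#' and (ii) the standard deviation of consecutive length differences.
#' Slopes are averaged across cilia to give `mean_slope` (the background
#' decline over the imaging period); the per-cilium difference SDs are
#' averaged to give `diff_sd` and maximized to give `max_diff_sd`. The
#' difference SD reflects measurement error between consecutive frames:
#' for i.i.d. per-measurement noise of SD sigma it converges to
#' sigma * sqrt(2).
#'
#' Raw lengths are used deliberately: smoothing would shrink the very
#' fluctuation the statistic is meant to capture.
#'
#' @param controls List of control [length_trajectory()] objects.
#' @param instant_threshold Instant-loss length threshold; `NULL` (default)
#'   uses the estimated `diff_sd`.
#' @param mean_slope_override Optional fixed slope replacing the estimate.
#' @return A [control_baseline()].
#' @export
estimate_baseline <- function(controls, instant_threshold = NULL,
                              mean_slope_override = NULL) {
  if (length(controls) == 0) {
    stop("baseline estimation requires at least one control trajectory")
  }
  slopes <- numeric(length(controls))
  dsds <- numeric(length(controls))
  for (i in seq_along(controls)) {
    tr <- controls[[i]]
    if (any(tr$lengths == 0)) {
      warning("control ", tr$cilium_id,
              " reaches length 0; controls should be non-disassembling",
              call. = FALSE)
    }
    tmin <- tr$times / 60
    slopes[i] <- stats::cov(tmin, tr$lengths) / stats::var(tmin)
    dsds[i] <- stats::sd(diff(tr$lengths))
  }
  mean_slope <- if (!is.null(mean_slope_override)) {
    mean_slope_override
  } else {
    mean(slopes)
  }
  diff_sd <- mean(dsds)
  thr <- if (!is.null(instant_threshold)) instant_threshold else diff_sd
  if (thr <= 1e-9) {
    # (near-)noiseless controls give diff_sd ~ 0, which would call any
    # positive penultimate length Instant; fall back to the literal constant
    thr <- .default_instant_threshold
  }
  control_baseline(
    mean_slope = mean_slope,
    diff_sd = diff_sd,
    max_diff_sd = max(dsds),
    instant_threshold = thr,
    n_controls = length(controls)
  )
}
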