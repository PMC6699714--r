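#' Construct a cilium length trajectory
#'
#' The atomic input of the pipeline: one cilium's length measured over time
#' from a live-cell movie, together with its cohort metadata. Times are
#' stored in seconds from movie start; lengths in micrometres. Negative
#' lengths are clipped to zero with a warning (they arise from measurement
#' artefacts, not biology), and a trajectory whose observed frame spacing
#' deviates from the nominal interval by more than 10\% at the median is
#' flagged irregular rather than rejected, because pre-event stretches are
#' sometimes sampled manually at 15--30 minute intervals.
#'
#' @param cilium_id Opaque identifier, unique within a condition.
#' @param times Strictly increasing acquisition times, seconds from movie
#'   start. At least 3 points.
#' @param lengths Cilium lengths, um, same length as `times`.
#' @param condition Condition label (e.g. `"serum_stimulated"`).
#' @param role `"control"` (non-disassembling, used for baseline
#'   calibration) or `"experimental"`.
#' @param frame_interval Nominal seconds between frames (30--90 in the
#'   source movies). Defaults to the median observed spacing.
#' @return An object of class `cilium_trajectory`: a list with fields
#'   `cilium_id`, `condition`, `role`, `times`, `lengths`,
#'   `frame_interval`, `irregular` (logical), `clipped` (count of clipped
#'   values).
#' @examples
#' tr <- length_trajectory("c1", times = c(0, 90, 180),
#'                         lengths = c(5, 5, 5))
#' tr$frame_interval
#' @export
length_trajectory <- function(cilium_id, times, lengths,
                              condition = "unspecified",
                              role = c("experimental", "control"),
                              frame_interval = NULL) {
  role <- match.arg(role)
  times <- as.numeric(times)
  lengths <- as.numeric(lengths)
  if (length(times) != length(lengths)) {
    stop("times and lengths must have the same number of points (",
         cilium_id, ")")
  }
  if (length(times) < 3) {
    stop("trajectory ", cilium_id, " has fewer than 3 points")
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing (", cilium_id, ")")
  }
  if (anyNA(times) || anyNA(lengths)) {
    stop("missing values in trajectory ", cilium_id)
  }
  clipped <- sum(lengths < 0)
  if (clipped > 0) {
    warning(clipped, " negative length value(s) clipped to 0 in ",
            cilium_id, call. = FALSE)
    lengths <- pmax(lengths, 0)
  }
  spacing <- stats::median(diff(times))
  if (is.null(frame_interval)) {
    frame_interval <- spacing
  }
  if (frame_interval <= 0) {
    stop("frame_interval must be positive (", cilium_id, ")")
  }
  irregular <- abs(spacing - frame_interval) > 0.1 * frame_interval
  structure(
    list(
      cilium_id = as.character(cilium_id),
      condition = as.character(condition),
      role = role,
      times = times,
      lengths = lengths,
      frame_interval = frame_interval,
      irregular = irregular,
      clipped = clipped
    ),
    class = "cilium_trajectory"
  )
}

#' @export
print.cilium_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cilium_trajectory> %s [%s/%s]: %d points, %.0f-%.0f s, %.2f-%.2f um%s\n",
    x$cilium_id, x$condition, x$role, length(x$times),
    min(x$times), max(x$times), min(x$lengths), max(x$lengths),
    if (isTRUE(x$irregular)) " (irregular spacing)" else ""
  ))
  invisible(x)
}

## Truncate a trajectory to indices 1..k, keeping metadata. Used by the
## event pipeline to smooth only the pre-drop ("alive") segment.
truncate_trajectory <- function(traj, k) {
  stopifnot(k >= 1, k <= length(traj$times))
  out <- traj
  out$times <- traj$times[seq_len(k)]
  out$lengths <- traj$lengths[seq_len(k)]
  out
}

n_points <- function(traj) length(traj$times)
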