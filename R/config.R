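#' Default analysis configuration
#'
#' Returns the full nested list of tunable parameters used across the
#' pipeline, with their shipped defaults. Every threshold of every stage
#' appears here, so a configuration file only needs to state the keys it
#' wants to change.
#'
#' Sections and keys:
#' \describe{
#'   \item{io}{\code{layout}: `"long"` (columns `cilium_id`, `time_s`,
#'     `length_um`) or `"wide"` (one block of columns per cilium).}
#'   \item{smoothing}{\code{window}: odd number of frames (default 5);
#'     \code{kernel}: `"gaussian"` (Gaussian-weighted moving average,
#'     sd = window/4 frames) or `"uniform"`.}
#'   \item{baseline}{\code{instant_threshold_override},
#'     \code{mean_slope_override}: set to a number to bypass control-based
#'     calibration. With no controls and no override the shipped literal
#'     constants are 1.532 um and -0.005 um/min.}
#'   \item{event}{\code{zero_tol}: length (um) at or below which a cilium is
#'     considered absent (default 0); \code{slope_tol_factor}: multiple of
#'     |mean control slope| below which a derivative counts as background
#'     (default 1); \code{noise_k}: width, in units of the calibrated
#'     consecutive-difference SD per minute, of an optional noise band added
#'     to the stopping rule (default 0 = off); \code{degenerate_policy}:
#'     class assigned to single-frame drops from below the instant threshold
#'     (default `"gradual"`).}
#'   \item{stats}{\code{alpha}: significance level of the normality screen
#'     (default 0.05); \code{t_variant}: `"welch"` or `"student"`.}
#'   \item{sim}{the synthetic-cohort generator defaults; see
#'     [simulation_config()].}
#' }
#'
#' @return A named nested list.
#' @seealso [read_config()], [simulation_config()]
#' @export
default_config <- function() {
  list(
    io = list(layout = "long"),
    smoothing = list(window = 5L, kernel = "gaussian"),
    baseline = list(
      instant_threshold_override = NULL,
      mean_slope_override = NULL
    ),
    event = list(
      zero_tol = 0,
      slope_tol_factor = 1,
      noise_k = 0,
      degenerate_policy = "gradual"
    ),
    stats = list(alpha = 0.05, t_variant = "welch"),
    sim = unclass(simulation_config())
  )
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) configuration file and merges it over
#' [default_config()]: keys present in the file replace the defaults, keys
#' absent from the file keep them. Unknown keys raise an error naming the
#' offending key, so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML or JSON file, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) {
    return(base)
  }
  if (!file.exists(path)) {
    stop("configuration file not found: ", path)
  }
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) {
    return(base)
  }
  merge_config(base, user, path = "")
}

#' Write a configuration file
#'
#' @param config A configuration list.
#' @param path Output path; written as YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## Recursive merge with unknown-key detection. `sim` is merged leniently
## because simulation_config() accepts free-form distribution overrides.
merge_config <- function(base, user, path) {
  if (!is.list(user)) {
    return(user)
  }
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base) && !grepl("^sim", path) && path != "sim") {
      stop("unknown configuration key: ", full)
    }
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

## Shipped literal constants: instant-loss length threshold (um) and mean
## control slope (um/min), used whenever no control cohort is available.
.default_instant_threshold <- 1.532
.default_mean_slope <- -0.005
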