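#' Read a cohort manifest
#'
#' A manifest assigns each trajectory to a condition and a role. It is a
#' delimited text file (CSV or TSV, autodetected from the extension) with
#' columns `cilium_id`, `condition`, `role` and optionally `source` (the
#' trajectory table the cilium lives in, when trajectories are split over
#' several files).
#'
#' @param path Path to the manifest file.
#' @return A data frame with columns `cilium_id`, `condition`, `role`,
#'   `source`.
#' @export
read_manifest <- function(path) {
  man <- read_delimited(path)
  need <- c("cilium_id", "condition", "role")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  man$cilium_id <- as.character(man$cilium_id)
  if (!"source" %in% names(man)) {
    man$source <- NA_character_
  }
  bad_role <- setdiff(unique(man$role), c("control", "experimental"))
  if (length(bad_role)) {
    stop("manifest role must be 'control' or 'experimental', got: ",
         paste(bad_role, collapse = ", "))
  }
  dup <- duplicated(man[c("cilium_id", "condition")])
  if (any(dup)) {
    stop("duplicate cilium_id within a condition: ",
         paste(unique(man$cilium_id[dup]), collapse = ", "))
  }
  man[c("cilium_id", "condition", "role", "source")]
}

#' Read length trajectories from a delimited table
#'
#' Reads per-cilium length-versus-time series from a CSV/TSV table and
#' attaches the metadata recorded in a manifest. Two layouts are supported:
#' \describe{
#'   \item{long}{columns `cilium_id`, `time_s`, `length_um`; one row per
#'     measurement.}
#'   \item{wide}{one block of two columns per cilium, named
#'     `<cilium_id>_time_s` and `<cilium_id>_length_um`; shorter
#'     trajectories are padded with empty cells.}
#' }
#' Negative lengths are clipped to zero with a warning. Trajectories with
#' fewer than 3 points are skipped with a warning; a cilium named in the
#' manifest but absent from the table is a hard error, as is non-monotone
#' time. Nothing is dropped silently: every input trajectory is either
#' returned or warned about.
#'
#' @param source Path to the trajectory table.
#' @param manifest Data frame from [read_manifest()].
#' @param layout `"long"` or `"wide"`.
#' @return A list of [length_trajectory()] objects, one per usable manifest
#'   entry.
#' @export
read_trajectories <- function(source, manifest, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  tab <- read_delimited(source)
  series <- if (layout == "long") split_long(tab) else split_wide(tab)

  out <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$cilium_id[i]
    if (!id %in% names(series)) {
      stop("manifest entry '", id, "' not found in ", source)
    }
    s <- series[[id]]
    if (nrow(s) < 3) {
      warning("trajectory ", id, " has fewer than 3 points; skipped",
              call. = FALSE)
      next
    }
    out[[id]] <- length_trajectory(
      cilium_id = id,
      times = s$time_s,
      lengths = s$length_um,
      condition = manifest$condition[i],
      role = manifest$role[i]
    )
  }
  extra <- setdiff(names(series), manifest$cilium_id)
  if (length(extra)) {
    warning("trajectories not listed in manifest were ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  out
}

split_long <- function(tab) {
  need <- c("cilium_id", "time_s", "length_um")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("long-layout table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  lapply(split(tab[c("time_s", "length_um")], as.character(tab$cilium_id)),
         function(s) s[stats::complete.cases(s), , drop = FALSE])
}

split_wide <- function(tab) {
  tcols <- grep("_time_s$", names(tab), value = TRUE)
  ids <- sub("_time_s$", "", tcols)
  if (!length(ids)) {
    stop("wide-layout table has no '<cilium_id>_time_s' columns")
  }
  series <- list()
  for (id in ids) {
    lcol <- paste0(id, "_length_um")
    if (!lcol %in% names(tab)) {
      stop("wide-layout table has '", id, "_time_s' but no '", lcol, "'")
    }
    s <- data.frame(time_s = tab[[paste0(id, "_time_s")]],
                    length_um = tab[[lcol]])
    series[[id]] <- s[stats::complete.cases(s), , drop = FALSE]
  }
  series
}

## CSV/TSV reader; delimiter autodetected from the file extension.
read_delimited <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "",
                    blank.lines.skip = TRUE)
}

## Fixed column order of the per-event results table.
events_table_columns <- c(
  "cilium_id", "condition", "class",
  "start_time_min", "end_time_min",
  "start_length_um", "penultimate_length_um", "max_length_um",
  "gradual_rate_um_per_min", "instant_min_rate_um_per_min",
  "fraction_gradual", "fraction_instant", "degenerate"
)

#' Write the per-event results table
#'
#' One row per classified loss event, numeric fields rounded to 4 decimals,
#' absent quantities (e.g. the gradual rate of a purely Instant event)
#' written as empty cells. The file round-trips losslessly at that
#' precision through [read_events_table()].
#'
#' @param events Events data frame from [analyze_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  out <- data.frame(cilium_id = character(0))
  if (nrow(events)) {
    out <- events
    for (col in setdiff(events_table_columns, names(out))) {
      out[[col]] <- NA
    }
    out <- out[events_table_columns]
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round, digits = 4)
  } else {
    for (col in events_table_columns) out[[col]] <- logical(0)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write events table to ", path, ": ",
         conditionMessage(ok))
  }
  invisible(path)
}

#' Read a per-event results table written by [write_events_table()]
#'
#' @param path Path to the CSV file.
#' @return Events data frame with numeric columns restored (empty cells
#'   become `NA`).
#' @export
read_events_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cilium_id = "character"))
  missing <- setdiff(events_table_columns, names(tab))
  if (length(missing)) {
    stop("events table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  numcols <- setdiff(events_table_columns,
                     c("cilium_id", "condition", "class", "degenerate"))
  for (col in numcols) tab[[col]] <- as.numeric(tab[[col]])
  tab$degenerate <- as.logical(tab$degenerate)
  tab
}
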