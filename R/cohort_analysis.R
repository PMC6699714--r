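#' Normalize a loss trajectory to common time and length scales
#'
#' Rescales time affinely so that movie start maps to 0 and the event's
#' completion point to 1,000 arbitrary units, and divides lengths by the
#' cilium's maximum length, so cohorts of cilia with different sizes and
#' event timings can be averaged. The trajectory is truncated at the
#' completion point. The detected event start is carried along as a marker
#' on the same normalized time axis.
#'
#' @param traj The [length_trajectory()] the event was detected on.
#' @param event One-row events data frame from [analyze_trajectory()]
#'   (must not be censored).
#' @return A `normalized_curve`: list with `norm_times` (0..1000),
#'   `norm_lengths` (max 1), `start_marker`, `cilium_id`, `class`.
#' @export
normalize_curve <- function(traj, event) {
  if (event$class == "censored" || is.na(event$completion_index)) {
    stop("cannot normalize a censored trajectory (", traj$cilium_id, ")")
  }
  comp <- event$completion_index
  idx <- seq_len(comp)
  lengths <- traj$lengths[idx]
  lmax <- max(lengths)
  if (lmax <= 0) {
    stop("maximum length is zero for ", traj$cilium_id)
  }
  t0 <- traj$times[1]
  span <- traj$times[comp] - t0
  norm_times <- 1000 * (traj$times[idx] - t0) / span
  structure(
    list(
      norm_times = norm_times,
      norm_lengths = lengths / lmax,
      start_marker = 1000 * (traj$times[event$start_index] - t0) / span,
      cilium_id = traj$cilium_id,
      class = event$class
    ),
    class = "normalized_curve"
  )
}

#' Average normalized curves on a common grid
#'
#' Each curve is linearly interpolated onto a shared 0--1000 grid and the
#' pointwise mean is taken. Start markers are returned as the raw list so
#' they can be drawn as individual points on the averaged curve.
#'
#' @param curves List of [normalize_curve()] results.
#' @param grid_n Number of grid points (default 1001).
#' @return List with `grid`, `mean_lengths`, `n` and `start_markers`.
#' @export
average_curves <- function(curves, grid_n = 1001L) {
  if (!length(curves)) {
    stop("average_curves requires at least one curve")
  }
  grid <- seq(0, 1000, length.out = grid_n)
  mat <- vapply(curves, function(cv) {
    stats::approx(cv$norm_times, cv$norm_lengths, xout = grid,
                  rule = 2)$y
  }, numeric(grid_n))
  list(
    grid = grid,
    mean_lengths = rowMeans(mat),
    n = length(curves),
    start_markers = vapply(curves, function(cv) cv$start_marker,
                           numeric(1))
  )
}

classified_events <- function(events) {
  events[events$class %in% c("gradual", "instant", "combined"), ,
         drop = FALSE]
}

#' Class counts and relative frequencies of loss behaviours
#'
#' Censored trajectories (cilia that never completed loss during imaging)
#' are excluded. `instant_terminal` is the fraction of events whose
#' terminal loss happens within a single frame, i.e. Instant plus
#' Combined.
#'
#' @param events Events data frame.
#' @return List with `counts` (named integer vector over gradual /
#'   instant / combined), `frequencies` (summing to 1), `n`,
#'   `n_censored` and `instant_terminal`.
#' @export
class_frequencies <- function(events) {
  ev <- classified_events(events)
  if (!nrow(ev)) {
    stop("no classified (non-censored) events")
  }
  lev <- c("gradual", "instant", "combined")
  counts <- table(factor(ev$class, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  n <- sum(counts)
  list(
    counts = counts,
    frequencies = counts / n,
    n = n,
    n_censored = sum(events$class == "censored"),
    instant_terminal = (counts[["instant"]] + counts[["combined"]]) / n
  )
}

#' Per-class rate summaries and pairwise rate comparisons
#'
#' Summarises loss rates as mean and SD for four samples: the gradual
#' rates of Gradual-only events, the instant minimum rates of Instant-only
#' events, and the two phases of Combined events taken separately. Three
#' pairwise two-sided unpaired t tests are reported: Combined gradual
#' phase vs Gradual-only, Combined instant phase vs Instant-only, and
#' Gradual-only vs Instant-only. A comparison with fewer than 2 values on
#' either side is skipped with a warning. No multiple-testing correction
#' is applied; the p-values are raw pairwise tests.
#'
#' @param events Events data frame.
#' @param t_variant `"welch"` (unequal variances, default) or
#'   `"student"`.
#' @return List with `summary` (data frame: group, n, mean, sd) and
#'   `tests` (data frame: comparison, statistic, p, test).
#' @export
rate_statistics <- function(events, t_variant = c("welch", "student")) {
  t_variant <- match.arg(t_variant)
  ev <- classified_events(events)
  groups <- list(
    gradual_only = ev$gradual_rate_um_per_min[ev$class == "gradual"],
    instant_only = ev$instant_min_rate_um_per_min[ev$class == "instant"],
    combined_gradual_phase =
      ev$gradual_rate_um_per_min[ev$class == "combined"],
    combined_instant_phase =
      ev$instant_min_rate_um_per_min[ev$class == "combined"]
  )
  groups <- lapply(groups, function(x) x[!is.na(x)])
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, function(x) if (length(x)) mean(x) else NA_real_,
                  numeric(1)),
    sd = vapply(groups, function(x) if (length(x) > 1) stats::sd(x)
                else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  pairs <- list(
    c("combined_gradual_phase", "gradual_only"),
    c("combined_instant_phase", "instant_only"),
    c("gradual_only", "instant_only")
  )
  tests <- lapply(pairs, function(p) {
    a <- groups[[p[1]]]
    b <- groups[[p[2]]]
    cmp <- paste(p, collapse = " vs ")
    if (length(a) < 2 || length(b) < 2) {
      warning("comparison skipped (fewer than 2 events per class): ", cmp,
              call. = FALSE)
      return(data.frame(comparison = cmp, statistic = NA_real_,
                        p = NA_real_, test = "skipped",
                        stringsAsFactors = FALSE))
    }
    tt <- unpaired_t(a, b, t_variant)
    data.frame(comparison = cmp, statistic = tt$statistic, p = tt$p,
               test = tt$test, stringsAsFactors = FALSE)
  })
  list(summary = summary, tests = do.call(rbind, tests))
}

unpaired_t <- function(a, b, t_variant) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # identical constant samples: no variance to test against
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = 0, p = if (same) 1 else NA_real_,
                test = "degenerate"))
  }
  ht <- stats::t.test(a, b, var.equal = (t_variant == "student"))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       test = if (t_variant == "student") "t (Student)" else "t (Welch)")
}

#' Hourly histogram of event start and end points
#'
#' Counts event start times and end times in fixed bins (default 60 min)
#' across the imaging window. Bins are left-closed: a time of exactly
#' 60 min falls in the 60--120 bin.
#'
#' @param events Events data frame.
#' @param bin_min Bin width in minutes.
#' @return Data frame with `bin_start_min`, `bin_end_min`, `n_start`,
#'   `n_end`. Empty input gives an all-zero single-bin histogram.
#' @export
timing_histogram <- function(events, bin_min = 60) {
  ev <- classified_events(events)
  tmax <- if (nrow(ev)) max(ev$end_time_min, ev$start_time_min) else 0
  edges <- seq(0, bin_min * (floor(tmax / bin_min) + 1), by = bin_min)
  lower <- edges[-length(edges)]
  bin_of <- function(t) findInterval(t, edges, rightmost.closed = FALSE)
  count <- function(t) tabulate(bin_of(t), nbins = length(lower))
  data.frame(
    bin_start_min = lower,
    bin_end_min = edges[-1],
    n_start = if (nrow(ev)) count(ev$start_time_min) else 0L,
    n_end = if (nrow(ev)) count(ev$end_time_min) else 0L
  )
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus test combining the transformed sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe & Glynn 1983) into a
#' chi-squared statistic with 2 degrees of freedom. Requires at least 8
#' observations for the kurtosis approximation to hold.
#'
#' @param x Numeric vector, `n >= 8`.
#' @return List with `statistic` (K2) and `p`.
#' @export
dagostino_pearson_test <- function(x) {
  n <- length(x)
  if (n < 8) {
    stop("D'Agostino-Pearson test requires at least 8 observations")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) {
    stop("zero variance sample")
  }
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness: D'Agostino's transformation to approximate normality
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn transformation
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

normality_screen <- function(x, alpha) {
  ps <- c(
    shapiro_wilk = tryCatch(stats::shapiro.test(x)$p.value,
                            error = function(e) NA_real_),
    kolmogorov_smirnov = tryCatch(
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
      ),
      error = function(e) NA_real_
    ),
    dagostino_pearson = if (length(x) >= 8) {
      tryCatch(dagostino_pearson_test(x)$p, error = function(e) NA_real_)
    } else {
      NA_real_
    }
  )
  data.frame(test = names(ps), p = unname(ps), pass = unname(ps >= alpha),
             stringsAsFactors = FALSE)
}

#' Normality-gated two-sample comparison
#'
#' Runs three normality tests (Shapiro-Wilk, a Kolmogorov-Smirnov test
#' against a normal with the sample's moments, and D'Agostino-Pearson)
#' on each group at level `alpha`. If every computable test passes on
#' both groups, an unpaired t test is used; if every test fails, the
#' Mann-Whitney U test; if the tests disagree, both are run and reported.
#' The D'Agostino-Pearson test needs at least 8 values and is excluded
#' from the gate below that.
#'
#' @param a,b Numeric vectors, at least 3 values each.
#' @param alpha Significance level of the normality screen.
#' @param t_variant `"welch"` or `"student"`.
#' @return List with `normality` (per-group test table), `decision`
#'   (`"t"`, `"mann_whitney"`, `"both"` or `"degenerate"`) and `tests`
#'   (data frame: test, statistic, p).
#' @export
compare_conditions <- function(a, b, alpha = 0.05,
                               t_variant = c("welch", "student")) {
  t_variant <- match.arg(t_variant)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("compare_conditions requires at least 3 values per group")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("both groups are constant; comparison is degenerate",
            call. = FALSE)
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(
      normality = NULL, decision = "degenerate",
      tests = data.frame(test = "degenerate", statistic = 0,
                         p = if (same) 1 else NA_real_,
                         stringsAsFactors = FALSE)
    ))
  }
  norm <- rbind(
    cbind(group = "a", normality_screen(a, alpha)),
    cbind(group = "b", normality_screen(b, alpha))
  )
  verdicts <- norm$pass[!is.na(norm$pass)]
  decision <- if (all(verdicts)) "t"
              else if (!any(verdicts)) "mann_whitney"
              else "both"

  run_t <- function() {
    tt <- unpaired_t(a, b, t_variant)
    data.frame(test = tt$test, statistic = tt$statistic, p = tt$p,
               stringsAsFactors = FALSE)
  }
  run_u <- function() {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(test = "Mann-Whitney U", statistic = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }
  tests <- switch(decision,
    t = run_t(),
    mann_whitney = run_u(),
    both = rbind(run_t(), run_u())
  )
  list(normality = norm, decision = decision, tests = tests)
}

#' Full cohort summary
#'
#' Bundles class frequencies, rate statistics and the hourly timing
#' histogram of an analysed cohort into one JSON-serialisable list.
#'
#' @param events Events data frame from [analyze_cohort()].
#' @param t_variant Passed to [rate_statistics()].
#' @param bin_min Passed to [timing_histogram()].
#' @return A named list.
#' @export
summarize_cohort <- function(events, t_variant = "welch", bin_min = 60) {
  freq <- class_frequencies(events)
  list(
    n_events = freq$n,
    n_censored = freq$n_censored,
    counts = as.list(freq$counts),
    frequencies = as.list(freq$frequencies),
    instant_terminal = freq$instant_terminal,
    rates = rate_statistics(events, t_variant = t_variant),
    timing = timing_histogram(events, bin_min = bin_min)
  )
}
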