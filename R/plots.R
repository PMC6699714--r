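#' Plot raw length trajectories
#'
#' @param trajectories List of [length_trajectory()] objects.
#' @return A ggplot object: length (um) versus time (min), one line per
#'   cilium.
#' @export
plot_trajectories <- function(trajectories) {
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(cilium_id = tr$cilium_id, time_min = tr$times / 60,
               length_um = tr$lengths)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$length_um,
                                   group = .data$cilium_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Time (min)", y = "Length (µm)") +
    ggplot2::theme_minimal()
}

#' Plot averaged normalized loss curves with event start markers
#'
#' Reproduces the cumulative normalized view: one mean curve per class on
#' the common 0--1000 time axis, with open circles at the individual
#' event start points (placed on the class mean curve).
#'
#' @param averages Named list of [average_curves()] results, one per
#'   class.
#' @return A ggplot object.
#' @export
plot_average_curves <- function(averages) {
  lines <- do.call(rbind, lapply(names(averages), function(cls) {
    av <- averages[[cls]]
    data.frame(class = cls, norm_time = av$grid,
               norm_length = av$mean_lengths)
  }))
  marks <- do.call(rbind, lapply(names(averages), function(cls) {
    av <- averages[[cls]]
    data.frame(class = cls, norm_time = av$start_markers,
               norm_length = stats::approx(av$grid, av$mean_lengths,
                                           xout = av$start_markers,
                                           rule = 2)$y)
  }))
  ggplot2::ggplot(lines, ggplot2::aes(.data$norm_time, .data$norm_length,
                                      colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks, shape = 1) +
    ggplot2::labs(x = "Normalized time (a.u.)", y = "Normalized length") +
    ggplot2::theme_minimal()
}

#' Stacked relative-frequency plot of loss behaviours
#'
#' @param frequencies Result of [class_frequencies()], or a named list of
#'   such results (one bar per condition).
#' @return A ggplot object.
#' @export
plot_class_frequencies <- function(frequencies) {
  if (!is.null(frequencies$counts)) {
    frequencies <- list(cohort = frequencies)
  }
  df <- do.call(rbind, lapply(names(frequencies), function(cond) {
    fr <- frequencies[[cond]]
    data.frame(condition = cond, class = names(fr$frequencies),
               frequency = as.numeric(fr$frequencies))
  }))
  df$class <- factor(df$class, levels = c("gradual", "combined", "instant"))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$frequency,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative frequency") +
    ggplot2::theme_minimal()
}

#' Dot plot of per-class loss rates
#'
#' Gradual-phase and instant-phase rates by class, on a log axis (rates
#' span several orders of magnitude).
#'
#' @param events Events data frame.
#' @return A ggplot object.
#' @export
plot_rate_distributions <- function(events) {
  ev <- classified_events(events)
  block <- function(group, rate) {
    data.frame(group = rep(group, length(rate)), rate = rate)
  }
  df <- rbind(
    block("gradual-only",
          ev$gradual_rate_um_per_min[ev$class == "gradual"]),
    block("combined: gradual phase",
          ev$gradual_rate_um_per_min[ev$class == "combined"]),
    block("combined: instant phase",
          ev$instant_min_rate_um_per_min[ev$class == "combined"]),
    block("instant-only",
          ev$instant_min_rate_um_per_min[ev$class == "instant"])
  )
  df <- df[!is.na(df$rate) & df$rate > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$rate)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, shape = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Rate (µm/min)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
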