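#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_ribbon scale_y_log10 labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a simulated batch culture
#'
#' OD (log scale), substrate concentrations and, when present, GFP over
#' time, faceted by channel.
#'
#' @param object a [simulate_batch()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.batch_sim <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = c("od", "gfp", "glucose_gl", "acetate_gl"),
                        names_to = "channel", values_to = "value")
  ggplot(long, aes(x = .data$time_h, y = .data$value)) +
    geom_line() +
    facet_wrap(~ .data$channel, scales = "free_y") +
    labs(x = "time (h)", y = NULL) +
    theme_minimal()
}

#' Plot growth curves from a plate
#'
#' ln-scale OD trajectories per well with the primary exponential-fit
#' window marked.
#'
#' @param plate a [read_plate_table()] result (or any tibble with `well`,
#'   `time_h`, `od`).
#' @param od_lo,od_hi window bounds drawn as horizontal guides.
#' @return a ggplot object.
#' @export
plot_growth_curves <- function(plate, od_lo = 0.05, od_hi = 0.35) {
  ggplot(plate, aes(x = .data$time_h, y = .data$od,
                    group = .data$well)) +
    geom_line(alpha = 0.7) +
    geom_hline(yintercept = c(od_lo, od_hi), linetype = "dashed",
               colour = "grey50") +
    scale_y_log10() +
    labs(x = "time (h)", y = "OD600 (calibrated, log scale)") +
    theme_minimal()
}

#' Plot an activity trajectory
#'
#' Transcriptional or promoter activity over time with the exponential-phase
#' OD window shaded points.
#'
#' @param traj a [transcriptional_activity()] or [promoter_activity()]
#'   result.
#' @param od_lo,od_hi OD bounds of the highlighted exponential phase.
#' @return a ggplot object.
#' @export
plot_activity <- function(traj, od_lo = 0.1, od_hi = 0.3) {
  value_col <- intersect(c("transcriptional", "promoter"), names(traj))[1L]
  traj$in_window <- traj$od >= od_lo & traj$od <= od_hi
  ggplot(traj, aes(x = .data$time_h, y = .data[[value_col]])) +
    geom_line() +
    geom_point(aes(colour = .data$in_window), size = 0.8) +
    labs(x = "time (h)", y = value_col, colour = "exponential phase") +
    theme_minimal()
}

#' Plot a competition trajectory
#'
#' Focal-genotype frequency per passage with Wilson 95% count intervals.
#'
#' @param object a [simulate_serial_passages()] result (or a data frame
#'   with `passage`, `focal_fraction` and optionally counts).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.competition_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot(df, aes(x = .data$passage, y = .data$focal_fraction))
  if (all(c("focal_count", "total_count") %in% names(df))) {
    ci <- frequency_from_counts(df$focal_count, df$total_count)
    df$lower <- ci$lower
    df$upper <- ci$upper
    p <- ggplot(df, aes(x = .data$passage, y = .data$focal_fraction)) +
      geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                  alpha = 0.2)
  }
  p + geom_line() + geom_point() +
    labs(x = "passage", y = "focal-genotype frequency") +
    theme_minimal()
}
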