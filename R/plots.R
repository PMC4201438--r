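#' Map of a stand
#'
#' Plots tree positions with point size proportional to dbh; the sampling
#' square and (if present) the impact strip are outlined.
#'
#' @param stand A [new_stand()] object.
#' @return A ggplot.
#' @export
plot_stand <- function(stand) {
  lo <- stand$sample_origin
  hi <- stand$sample_origin + stand$sample_side
  p <- ggplot2::ggplot(stand$trees, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::annotate("rect", xmin = lo, xmax = hi, ymin = lo, ymax = hi,
                      fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$dbh), alpha = 0.5,
                        colour = "darkgreen") +
    ggplot2::scale_size_area(max_size = 3, name = "dbh (cm)") +
    ggplot2::coord_fixed(xlim = c(0, stand$domain_side),
                         ylim = c(0, stand$domain_side)) +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("Stand, year %d", stand$year))
  if (!is.null(stand$zone)) {
    p <- p + ggplot2::annotate("rect",
      xmin = stand$zone$x_min, xmax = stand$zone$x_max,
      ymin = 0, ymax = stand$domain_side,
      fill = "firebrick", alpha = 0.1, colour = "firebrick"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Biomass trajectory of a simulation
#'
#' @param object A `sim_result` from [simulate_years()] or [spinup()].
#' @param band Healthy-biomass band to shade (t/ha); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_result <- function(object, band = c(300, 400), ...) {
  p <- ggplot2::ggplot(object$trajectory,
                       ggplot2::aes(.data$year, .data$biomass_t_ha))
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = band[1], ymax = band[2],
                               fill = "steelblue", alpha = 0.15)
  }
  p + ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "year", y = "biomass (t/ha)")
}

#' Replicate recovery times for one scenario
#'
#' @param object A `recovery_result` from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$impact, .data$years)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$censored),
                        position = ggplot2::position_jitter(width = 0.1),
                        alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "recovery time (years)")
}

#' Boxplot of recovery times across impacts
#'
#' @param results The tibble returned by [run_all()] (with its `replicates`
#'   list-column).
#' @return A ggplot.
#' @export
plot_recovery_times <- function(results) {
  long <- results |>
    dplyr::select("impact", "replicates") |>
    tidyr::unnest("replicates")
  ggplot2::ggplot(
    long,
    ggplot2::aes(stats::reorder(.data$impact, .data$years, median),
                 .data$years)
  ) +
    ggplot2::geom_boxplot(fill = "darkseagreen2") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "recovery time (years)")
}

#' Bar chart of a weighted Likert ranking
#'
#' @param scores Output of [weighted_likert_scores()].
#' @return A ggplot.
#' @export
plot_likert_ranking <- function(scores) {
  ggplot2::ggplot(
    scores,
    ggplot2::aes(stats::reorder(.data$option, .data$pct), .data$pct)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "weighted score (% of maximum)")
}
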