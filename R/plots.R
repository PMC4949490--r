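# ggplot2 visualizations for cohorts, fitted trajectories, contrasts and
# sensitivity curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed cohort trajectories
#'
#' Spaghetti plot of performance over trials, one line per individual,
#' colored by ITA group.
#'
#' @param object A cohort tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spiral_cohort
#' @export
autoplot.spiral_cohort <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$trial, y = .data$score,
    group = .data$individual, colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(entity = "firebrick", incremental = "steelblue")) +
    ggplot2::labs(x = "trial", y = "performance score", colour = NULL)
}

#' Plot per-individual spiral probabilities
#'
#' @param object A `spiral_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spiral_report
#' @export
autoplot.spiral_report <- function(object, ...) {
  ggplot2::ggplot(object$individuals, ggplot2::aes(
    x = stats::reorder(.data$individual, .data$pr_spiral),
    y = .data$pr_spiral, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(entity = "firebrick", incremental = "steelblue")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior probability of spiraling",
                  colour = NULL)
}

#' Plot a model-averaged fitted trajectory
#'
#' Posterior-mean trajectory for one individual, optionally overlaid on the
#' observed scores.
#'
#' @param draws A `spiral_draws` tibble.
#' @param individual Individual id.
#' @param cohort Optional cohort tibble with the observed scores.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(draws, individual, cohort = NULL) {
  ft <- fitted_trajectory(draws, individual)
  p <- ggplot2::ggplot(ft$trajectory,
                       ggplot2::aes(x = .data$trial, y = .data$mean)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "trial", y = "performance score",
                  title = paste0("individual ", individual,
                                 " (Pr spiral = ",
                                 signif(ft$pr_spiral, 2), ")"))
  if (!is.null(cohort)) {
    obs <- cohort[cohort$individual == as.character(individual), ]
    p <- p + ggplot2::geom_point(
      data = obs, ggplot2::aes(x = .data$trial, y = .data$score),
      inherit.aes = FALSE, shape = 8)
  }
  p
}

#' Plot a posterior contrast histogram
#'
#' @param object A `slope_contrast` or `pi_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slope_contrast
#' @export
autoplot.slope_contrast <- function(object, ...) {
  ggplot2::ggplot(object$hist,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "slope-mean difference (entity - incremental)",
                  y = "draws")
}

#' @rdname autoplot.slope_contrast
#' @method autoplot pi_contrast
#' @export
autoplot.pi_contrast <- function(object, ...) {
  ggplot2::ggplot(object$hist,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "spiral-propensity difference (entity - incremental)",
                  y = "draws")
}

#' Plot a prior-sensitivity curve
#'
#' @param object A `sensitivity_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_curve
#' @export
autoplot.sensitivity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c_delta,
                                       y = .data$pr_entity_above)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "prior variance of the propensity coefficients",
                  y = "Pr(entity propensity > incremental | data)")
}
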