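#' Plot an equating result
#'
#' Draws the continuous equated function together with the rounded integer
#' crosswalk and the identity line; the vertical gap to the identity shows
#' the relative difficulty of the two tests at each score level.
#'
#' @param object An `equating_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.equating_result <- function(object, ...) {
  m <- object$metadata
  df <- object$concordance
  names(df)[1] <- "score"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$equated), colour = "#2166ac") +
    ggplot2::geom_step(ggplot2::aes(y = .data$converted), colour = "#b2182b",
                       alpha = 0.7) +
    ggplot2::labs(
      x = paste0(m$x_name, " score"),
      y = paste0("equated ", m$y_name, " score"),
      title = "Equipercentile concordance",
      subtitle = "blue: continuous equated values; red: rounded crosswalk"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a presmoothing fit
#'
#' Observed score proportions (bars) with the fitted log-linear
#' probabilities (line and points) over the full support.
#'
#' @param object A `loglinear_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.loglinear_fit <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prop), fill = "grey70",
                      width = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_prob), colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$fitted_prob), colour = "#2166ac",
                        size = 1) +
    ggplot2::labs(x = "score", y = "probability",
                  title = paste0("Log-linear presmoothing (degree ",
                                 object$degree, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' Observed versus crosswalk-estimated MMSE scores, with the identity line
#' and the +/-1 and +/-2 point agreement bands, coloured by clinical group.
#'
#' @param object A `validation_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mmse, y = .data$estimated_mmse)) +
    ggplot2::geom_ribbon(
      data = tibble(mmse = 0:30),
      ggplot2::aes(x = .data$mmse, ymin = .data$mmse - 2, ymax = .data$mmse + 2),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_ribbon(
      data = tibble(mmse = 0:30),
      ggplot2::aes(x = .data$mmse, ymin = .data$mmse - 1, ymax = .data$mmse + 1),
      inherit.aes = FALSE, fill = "grey75", alpha = 0.6
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$clinical),
                         width = 0.15, height = 0.15, alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 30), ylim = c(0, 30)) +
    ggplot2::labs(x = "observed MMSE", y = "estimated MMSE (via crosswalk)",
                  colour = NULL,
                  title = "Crosswalk validation",
                  subtitle = sprintf("ICC = %.2f; within ±1: %.0f%%, ±2: %.0f%%",
                                     object$overall$icc,
                                     object$overall$pct_within_1,
                                     object$overall$pct_within_2)) +
    ggplot2::theme_minimal()
}

#' Plot the two score distributions of a cohort
#'
#' Side-by-side frequency distributions of the RUDAS and MMSE scores.
#'
#' @param cohort A cohort tibble.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(cohort) {
  cohort <- as_cohort(cohort)
  long <- tidyr::pivot_longer(cohort, c("rudas", "mmse"),
                              names_to = "test", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_bar(fill = "#2166ac") +
    ggplot2::facet_wrap(~test, ncol = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 30)) +
    ggplot2::labs(x = "score", y = "count") +
    ggplot2::theme_minimal()
}
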