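#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_hline geom_jitter geom_errorbar facet_wrap labs theme_minimal
#'   scale_y_log10 coord_fixed scale_fill_manual position_dodge
#'   geom_point position_jitterdodge
NULL

#' @export
ggplot2::autoplot

#' Plot a stimulus display
#'
#' @param object a `stim_image`.
#' @param ... unused.
#' @return A ggplot raster of the display (black ink on white).
#' @method autoplot stim_image
#' @export
autoplot.stim_image <- function(object, ...) {
  d <- tidyr::expand_grid(y = seq_len(object$height), x = seq_len(object$width))
  d$ink <- as.vector(t(object$pixels))
  ggplot(d, aes(.data$x, -.data$y, fill = factor(.data$ink))) +
    geom_raster(show.legend = FALSE) +
    scale_fill_manual(values = c(`0` = "white", `1` = "black")) +
    coord_fixed() +
    labs(title = sprintf("%d element(s), %s", object$n_elements,
                         object$shape_kind),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a radially averaged power spectrum
#'
#' @param object a `power_spectrum` tibble from [radial_power_spectrum()].
#' @param ... unused.
#' @return A ggplot line plot, log-scaled power vs radial frequency.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot(object, aes(.data$freq, .data$power + 1e-12)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "radial frequency (cycles/image)", y = "mean power",
         title = "Radially averaged power spectrum") +
    theme_minimal()
}

#' Plot an experiment summary
#'
#' Bar chart of mean preference per test with per-bee points, s.e.m. bars
#' and the 0.5 chance line, one panel per test, bars split by rule group.
#'
#' @param object a `bee_experiment` from [run_population()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot bee_experiment
#' @export
autoplot.bee_experiment <- function(object, ...) {
  summ <- dplyr::filter(object$summary, .data$rule != "pooled",
                        .data$statistic_name == "wilcoxon_z")
  scores <- object$scores
  ggplot(summ, aes(.data$rule, .data$mean_pref, fill = .data$rule)) +
    geom_col(width = 0.6, show.legend = FALSE) +
    geom_errorbar(aes(ymin = .data$mean_pref - .data$sem,
                      ymax = .data$mean_pref + .data$sem), width = 0.2) +
    geom_jitter(data = scores, aes(.data$rule, .data$choice_fraction),
                width = 0.12, alpha = 0.4, size = 0.8, inherit.aes = FALSE) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    facet_wrap(~test) +
    scale_fill_manual(values = c(more_than = "grey30", less_than = "grey70")) +
    labs(x = NULL, y = "choice proportion (correct side)",
         title = sprintf("Model-bee battery: %s", object$config$experiment)) +
    theme_minimal()
}
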