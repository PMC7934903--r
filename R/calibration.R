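#' Calibrate the spatial-frequency-to-s mapping
#'
#' The magnitude network reads a single scalar input `s` on the 0-6 axis.
#' Displays are mapped onto that axis through their spatial-frequency power:
#' a least-squares affine map from the mean `sf_power` per element count to
#' the count value, constrained through the origin so that an empty display
#' (which has zero power in every non-DC bin) maps exactly to `s = 0`. The
#' constrained fit is therefore proportional: `s = beta * sf_power` with
#' `beta = sum(count * mean_power) / sum(mean_power^2)`.
#'
#' The calibration is estimated once on a training stimulus set and reused
#' unchanged for every test display of the experiment.
#'
#' @param cue_data tibble with columns `n_elements` and `sf_power`, counts
#'   1-6 (or the trained subrange) represented.
#' @return Object of class `s_calibration`: the slope `beta` and the
#'   per-count mean-power table.
#' @export
calibrate_s_mapping <- function(cue_data) {
  stopifnot(is.data.frame(cue_data),
            all(c("n_elements", "sf_power") %in% names(cue_data)))
  d <- dplyr::filter(cue_data, .data$n_elements >= 1)
  if (nrow(d) < 2 || length(unique(d$n_elements)) < 2) {
    abort("calibration needs displays spanning at least two element counts")
  }
  tab <- d |>
    dplyr::group_by(.data$n_elements) |>
    dplyr::summarise(mean_sf_power = mean(.data$sf_power), .groups = "drop")
  if (stats::sd(tab$mean_sf_power) < 1e-12 * mean(tab$mean_sf_power)) {
    abort("degenerate calibration: sf_power does not vary with element count",
          class = "magbee_calibration_error")
  }
  beta <- sum(tab$n_elements * tab$mean_sf_power) / sum(tab$mean_sf_power^2)
  structure(list(beta = beta, table = tab), class = "s_calibration")
}

#' @export
print.s_calibration <- function(x, ...) {
  cat(sprintf("<s_calibration> s = %.4g * sf_power (empty display -> s = 0)\n",
              x$beta))
  print(x$table)
  invisible(x)
}

#' Map spatial-frequency power to the model input axis
#'
#' @param calibration an `s_calibration` object.
#' @param sf_power numeric vector of spatial-frequency power values.
#' @return Calibrated scalar input(s) `s` on the 0-6 axis.
#' @export
s_input <- function(calibration, sf_power) {
  stopifnot(inherits(calibration, "s_calibration"))
  calibration$beta * sf_power
}

#' @export
predict.s_calibration <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$sf_power
  s_input(object, newdata)
}

#' Cue covariation with element count
#'
#' Spearman rank correlation of each continuous cue against the element
#' count across a stimulus set, one row per cue. This is the diagnostic
#' that shows which non-numerical cues a constant-area numerosity design
#' leaves available: with total area clamped, edge length, convex hull and
#' spatial-frequency power still track the count.
#'
#' @param cue_data tibble with `n_elements` and the cue columns.
#' @param cues character vector of cue column names to correlate.
#' @return Tibble: `cue`, `rho`, `p`, `n`.
#' @export
cue_covariation <- function(cue_data,
                            cues = c("area", "edge_length",
                                     "convex_hull_area", "sf_power")) {
  stopifnot(is.data.frame(cue_data), "n_elements" %in% names(cue_data))
  if (nrow(cue_data) < 10 || length(unique(cue_data$n_elements)) < 2) {
    abort("need >= 10 displays spanning >= 2 element counts")
  }
  purrr::map_dfr(cues, function(cue) {
    res <- spearman_rank(cue_data$n_elements, cue_data[[cue]])
    tibble(cue = cue, rho = res$rho, p = res$p, n = res$n)
  })
}
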