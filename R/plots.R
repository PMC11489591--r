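#' Calibration panels: measured, normalised and corrected Mg/Ca
#'
#' Three-panel view of a calibration set against a fitted model: measured
#' Mg/Ca vs temperature with the temperature-only prediction, normalised
#' Mg/Ca vs carbonate ion with the fitted power-law sensitivity, and
#' corrected Mg/Ca vs temperature with the corrected exponential calibration.
#'
#' @param samples Standardised sample tibble (`mgca_mmolmol`, `temp_C`,
#'   `co3_umolkg`).
#' @param model A [calibration_model()].
#' @return A ggplot object (facetted).
#' @export
plot_calibration <- function(samples, model) {
  stopifnot(is.data.frame(samples), inherits(model, "calibration_model"))
  s <- dplyr::filter(samples, is.finite(.data$mgca_mmolmol),
                     is.finite(.data$temp_C), is.finite(.data$co3_umolkg))
  s$mgca_norm <- normalize_mgca(s$mgca_mmolmol, s$temp_C, model$pred_law)
  s$mgca_corr <- suppressWarnings(
    correct_mgca(s$mgca_mmolmol, s$co3_umolkg, model$power_law))
  tgrid <- seq(min(s$temp_C), max(s$temp_C), length.out = 100)
  cgrid <- seq(min(s$co3_umolkg), max(s$co3_umolkg), length.out = 100)
  pts <- dplyr::bind_rows(
    tibble(panel = "measured vs T", x = s$temp_C, y = s$mgca_mmolmol),
    tibble(panel = "normalised vs [CO3]", x = s$co3_umolkg, y = s$mgca_norm),
    tibble(panel = "corrected vs T", x = s$temp_C, y = s$mgca_corr)
  )
  lines <- dplyr::bind_rows(
    tibble(panel = "measured vs T", x = tgrid,
           y = predict_mgca(tgrid, model$pred_law)),
    tibble(panel = "normalised vs [CO3]", x = cgrid,
           y = suppressWarnings(co3_sensitivity(cgrid, model$power_law))),
    tibble(panel = "corrected vs T", x = tgrid,
           y = predict_mgca(tgrid, model$exp_law))
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = lines, colour = "firebrick") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "Mg/Ca (mmol/mol) / normalised") +
    ggplot2::theme_minimal()
}

#' Equilibrium calcite d18O profile with matched calcification depths
#'
#' @param eq An [equilibrium_profile()] tibble.
#' @param estimates Optional [infer_calcification_depth()] output to overlay.
#' @return A ggplot object (depth increasing downwards).
#' @export
plot_equilibrium_profile <- function(eq, estimates = NULL) {
  p <- ggplot2::ggplot(eq, ggplot2::aes(x = .data$d18Oc_eq_permil,
                                        y = .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "equilibrium d18Oc (permil VPDB)", y = "depth (m)") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    est <- dplyr::filter(estimates, .data$matched)
    p <- p + ggplot2::geom_point(
      data = est,
      ggplot2::aes(x = .data$measured_d18Oc, y = .data$depth_m),
      colour = "firebrick")
  }
  p
}

#' @describeIn plot_sst_series autoplot method for reconstructed series
#' @param object,x A [reconstruct_sst()] output tibble.
#' @param ... Unused.
#' @method autoplot sst_series
#' @export
autoplot.sst_series <- function(object, ...) plot_sst_series(object, ...)

#' Downcore SST series with uncertainty ribbon
#'
#' Plots the reconstructed SST series against age with its 95% Monte Carlo
#' ribbon (when present) and the three-point running average.
#'
#' @return A ggplot object.
#' @export
plot_sst_series <- function(x, ...) {
  stopifnot(is.data.frame(x))
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$age_ka, y = .data$sst_C))
  if (all(c("sst_lo95", "sst_hi95") %in% names(x)) &&
      any(is.finite(x$sst_lo95))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$sst_lo95, ymax = .data$sst_hi95),
      fill = "steelblue", alpha = 0.25)
  }
  p <- p + ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8)
  if ("sst_smooth3" %in% names(x)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$sst_smooth3),
                                colour = "purple", linewidth = 0.9)
  }
  p + ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (ka)", y = "SST (deg C)") +
    ggplot2::theme_minimal()
}

#' Coefficient distributions of a Monte Carlo calibration ensemble
#'
#' @param object An [mc_calibration_ensemble()] result.
#' @param ... Unused.
#' @return A ggplot object with one histogram per coefficient.
#' @method autoplot mc_ensemble
#' @export
autoplot.mc_ensemble <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, cols = c("p", "q", "a", "b"),
                              names_to = "coefficient", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~coefficient, scales = "free") +
    ggplot2::labs(x = NULL, y = "draws") +
    ggplot2::theme_minimal()
}
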