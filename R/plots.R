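# ggplot2 views of the main result types.

#' Plot a spatial calibration map
#'
#' @param map A \code{\link{conversion_map}}.
#' @return A ggplot object (points coloured by conversion factor).
#' @export
plot_conversion_map <- function(map) {
  stopifnot(inherits(map, "conversion_map"))
  ggplot2::ggplot(map$points,
                  ggplot2::aes(.data$x_um, .data$y_um,
                               colour = .data$c_pN_per_pct2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "c [pN/%²]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [µm]", y = "y [µm]",
                  title = sprintf("Spatial calibration map (%d → %d beads)",
                                  map$n_raw, map$n_merged)) +
    ggplot2::theme_minimal()
}

#' Plot a modulus time series
#'
#' Storage and loss moduli per frequency over the analysis windows;
#' independent windows are drawn as filled points, overlapping windows as
#' crosses.
#'
#' @param spectra Aggregated series from \code{\link{aggregate_beads}}.
#' @return A ggplot object.
#' @export
plot_modulus_series <- function(spectra) {
  long <- spectra |>
    tidyr::pivot_longer(c("G1_Pa", "G2_Pa"), names_to = "component",
                        values_to = "G_Pa") |>
    dplyr::mutate(component = ifelse(.data$component == "G1_Pa",
                                     "G' (storage)", "G'' (loss)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_center_s, .data$G_Pa,
                                     colour = factor(.data$freq_hz),
                                     shape = .data$independent)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                name = "independent") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "window centre [s]", y = "modulus [Pa]",
                  colour = "f [Hz]") +
    ggplot2::theme_minimal()
}

#' Plot a modulus spectrum with fractional-model fits
#'
#' @param spectrum Tibble with \code{freq_hz}, \code{G1_Pa}, \code{G2_Pa}
#'   (one window or a time average).
#' @param gkv Optional \code{gkv_fit} overlaid as lines.
#' @return A ggplot object (log-log).
#' @export
plot_modulus_spectrum <- function(spectrum, gkv = NULL) {
  long <- spectrum |>
    tidyr::pivot_longer(c("G1_Pa", "G2_Pa"), names_to = "component",
                        values_to = "G_Pa")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$freq_hz, .data$G_Pa,
                                          colour = .data$component)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(G1_Pa = "#1b6ca8", G2_Pa = "#c0392b"),
      labels = c(G1_Pa = "G'", G2_Pa = "G''"), name = NULL) +
    ggplot2::labs(x = "frequency [Hz]", y = "modulus [Pa]") +
    ggplot2::theme_minimal()
  if (!is.null(gkv)) {
    fg <- seq(log10(min(spectrum$freq_hz) / 2),
              log10(max(spectrum$freq_hz) * 2), length.out = 100)
    G <- gkv_modulus(2 * pi * 10^fg, gkv$G0, gkv$alpha, gkv$beta)
    fit_df <- tibble::tibble(
      freq_hz = rep(10^fg, 2),
      G_Pa = c(Re(G), Im(G)),
      component = rep(c("G1_Pa", "G2_Pa"), each = length(fg)))
    p <- p + ggplot2::geom_line(data = fit_df, linewidth = 0.4)
  }
  p
}

#' Autoplot method for GKV fits
#'
#' @param object A \code{gkv_fit}.
#' @param spectrum The spectrum the fit was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gkv_fit <- function(object, spectrum, ...) {
  plot_modulus_spectrum(spectrum, gkv = object)
}
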