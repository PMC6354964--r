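#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result objects: power
#' spectra (log power), wavelet spectrograms (raster with the time-averaged
#' profile available via `tidy`-like access), imaginary coherence with its
#' surrogate threshold, cross-covariance curves with the global significance
#' band, and circular phase-lag histograms.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @method autoplot nc_psd
#' @export
autoplot.nc_psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(Power ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot nc_spectrogram
#' @export
autoplot.nc_spectrogram <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(object$times, times = length(object$freqs)),
    freq = rep(object$freqs, each = length(object$times)),
    power = as.vector(t(object$power)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)",
                  fill = expression(mu * V^2)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot nc_coherence
#' @export
autoplot.nc_coherence <- function(object, ...) {
  df <- tidy.nc_coherence(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_line(ggplot2::aes(y = abs(.data$icoh))) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), linetype = 2,
                       colour = "grey50") +
    ggplot2::labs(x = "Frequency (Hz)", y = "|imaginary coherence|") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot nc_crosscov
#' @export
autoplot.nc_crosscov <- function(object, ...) {
  df <- tidy.nc_crosscov(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$z)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag (ms, negative = first train leads)",
                  y = "Standardized cross-covariance (z)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot nc_phase_lag
#' @export
autoplot.nc_phase_lag <- function(object, ...) {
  df <- tidy.nc_phase_lag(object)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$breaks)[1L]) +
    ggplot2::coord_polar(start = pi) +
    ggplot2::labs(x = "Phase difference (rad)", y = "Count") +
    ggplot2::theme_minimal()
}
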