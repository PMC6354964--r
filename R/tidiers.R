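#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-element table of a result
#' object (one row per lag, frequency or test), `glance()` a one-row
#' summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy nc_test
#' @export
tidy.nc_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p.value = x$p, n = paste(x$n, collapse = "/"),
                 correction = x$correction)
}

#' @rdname tidiers
#' @method tidy nc_crosscov
#' @export
tidy.nc_crosscov <- function(x, ...) {
  tibble::tibble(lag_ms = x$lags_ms, z = x$z,
                 significant = abs(x$z) > x$threshold)
}

#' @rdname tidiers
#' @method glance nc_crosscov
#' @export
glance.nc_crosscov <- function(x, ...) {
  pk <- if (length(x$sig_lags_ms)) {
    si <- which(x$lags_ms %in% x$sig_lags_ms)
    x$lags_ms[si[which.max(abs(x$z[si]))]]
  } else {
    NA_real_
  }
  tibble::tibble(peak_lag_ms = pk, peak_z = if (is.na(pk)) NA_real_ else
    x$z[x$lags_ms == pk], threshold = x$threshold,
    n_sig_lags = length(x$sig_lags_ms), n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidiers
#' @method tidy nc_coherence
#' @export
tidy.nc_coherence <- function(x, ...) {
  tibble::tibble(freq = x$freq, icoh = x$icoh, threshold = x$threshold,
                 significant = abs(x$icoh) > x$threshold)
}

#' @rdname tidiers
#' @method glance nc_coherence
#' @export
glance.nc_coherence <- function(x, ...) {
  out <- tidyr::pivot_wider(x$band_means, names_from = "name",
                            values_from = "mean_abs_icoh",
                            names_prefix = "icoh_")
  out$n_surrogates <- x$n_surrogates
  out
}

#' @rdname tidiers
#' @method tidy nc_phase_lag
#' @export
tidy.nc_phase_lag <- function(x, ...) {
  tibble::tibble(bin_lo = x$breaks[-length(x$breaks)],
                 bin_hi = x$breaks[-1L], count = x$counts)
}

#' @rdname tidiers
#' @method glance nc_phase_lag
#' @export
glance.nc_phase_lag <- function(x, ...) {
  tibble::tibble(circ_mean = x$circ_mean, resultant = x$resultant, n = x$n)
}
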