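#' Frequency band definitions
#'
#' Construct a frequency band, or retrieve the canonical band set used
#' throughout the package: respiration-related rhythm (RR) 2-4 Hz, theta
#' 4-12 Hz, beta 15-30 Hz, gamma 30-80 Hz and a 1-100 Hz broadband.
#'
#' @param name Band name.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return `nc_band()` returns a one-row tibble with columns `name`, `f_lo`,
#'   `f_hi`; `nc_bands()` returns the canonical five-band tibble; `band()`
#'   returns one canonical band by name.
#' @examples
#' band("theta")
#' nc_bands()
#' @export
nc_band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.finite(f_lo) && is.finite(f_hi) && f_lo > 0 && f_hi > f_lo)) {
    stop("invalid band: need 0 < f_lo < f_hi", call. = FALSE)
  }
  tibble::tibble(name = name, f_lo = f_lo, f_hi = f_hi)
}

#' @rdname nc_band
#' @export
nc_bands <- function() {
  dplyr::bind_rows(
    nc_band("rr", 2, 4),
    nc_band("theta", 4, 12),
    nc_band("beta", 15, 30),
    nc_band("gamma", 30, 80),
    nc_band("broad", 1, 100)
  )
}

#' @rdname nc_band
#' @export
band <- function(name) {
  b <- nc_bands()
  out <- b[b$name == name, ]
  if (nrow(out) == 0L) {
    stop("unknown band '", name, "'; see nc_bands()", call. = FALSE)
  }
  out
}

check_band <- function(band, fs) {
  stopifnot(is.data.frame(band), all(c("f_lo", "f_hi") %in% names(band)))
  if (band$f_hi >= fs / 2) {
    stop("band edge ", band$f_hi, " Hz is at or above Nyquist (fs = ", fs,
         " Hz)", call. = FALSE)
  }
  invisible(band)
}
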