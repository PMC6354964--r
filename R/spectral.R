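#' Zero-phase band-pass filtering
#'
#' Band-pass filters a signal with a 3rd-order Butterworth filter applied
#' forward and backward (`signal::filtfilt`), so the output has zero phase
#' delay. Zero phase is required because downstream phase-locking and
#' phase-lag analyses assume the filter introduces no shift.
#'
#' @param x Numeric signal (one channel).
#' @param fs Sampling rate in Hz.
#' @param band A band tibble, e.g. `band("theta")` or `nc_band("x", 4, 30)`.
#' @param order Filter order (applied twice; effective roll-off doubles).
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 200
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 8 * t)
#' y <- bandpass_filter(x, fs, band("theta"))
#' @export
bandpass_filter <- function(x, fs, band, order = 3) {
  check_band(band, fs)
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Welch periodogram machinery shared by PSD, band power and coherence.
# Hann-tapered segments, 50% overlap by default, one-sided density scaling.
welch_segments <- function(n, fs, window_s, overlap) {
  nper <- round(window_s * fs)
  if (nper < 8) stop("Welch window too short", call. = FALSE)
  if (n < nper) {
    stop("signal shorter than one Welch window (", window_s, " s)",
         call. = FALSE)
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  list(nper = nper, starts = starts, win = 0.5 - 0.5 * cos(2 * pi *
    seq_len(nper) / (nper + 1)))
}

# Averaged one- or cross-spectral density over Welch segments.
welch_spectra <- function(x, y = NULL, fs, window_s = 4, overlap = 0.5,
                          demean = TRUE) {
  n <- length(x)
  seg <- welch_segments(n, fs, window_s, overlap)
  nper <- seg$nper
  u <- sum(seg$win^2)
  nf <- nper %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / nper
  sxx <- numeric(nf)
  syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in seg$starts) {
    xs <- x[s:(s + nper - 1L)]
    if (demean) xs <- xs - mean(xs)
    fx <- stats::fft(xs * seg$win)[seq_len(nf)]
    sxx <- sxx + Mod(fx)^2
    if (!is.null(y)) {
      ys <- y[s:(s + nper - 1L)]
      if (demean) ys <- ys - mean(ys)
      fy <- stats::fft(ys * seg$win)[seq_len(nf)]
      syy <- syy + Mod(fy)^2
      sxy <- sxy + fx * Conj(fy)
    }
  }
  k <- length(seg$starts)
  scale <- 1 / (k * fs * u)
  # one-sided density: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[nf] <- 1
  out <- list(freq = freq, sxx = sxx * scale * dbl, df = fs / nper,
              n_segments = k)
  if (!is.null(y)) {
    out$syy <- syy * scale * dbl
    out$sxy <- sxy * scale * dbl
  }
  out
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, 50%-overlapping segments
#' (4 s windows by default, resolving the 2 Hz lower edge of the
#' respiration-related band).
#'
#' @inheritParams bandpass_filter
#' @param window_s Segment length in seconds.
#' @param overlap Fractional segment overlap.
#' @return A tibble of class `nc_psd` with columns `freq` (Hz) and
#'   `power` (signal units squared per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  w <- welch_spectra(x, NULL, fs, window_s, overlap)
  out <- tibble::tibble(freq = w$freq, power = w$sxx)
  class(out) <- c("nc_psd", class(out))
  attr(out, "df") <- w$df
  out
}

#' Band-limited area power
#'
#' Integrates the Welch power spectral density over a frequency band,
#' returning area power in the units the field reports (microvolts squared
#' for a microvolt LFP). By Parseval's identity this approximates the
#' variance of the band-limited component.
#'
#' @inheritParams welch_psd
#' @param band Band tibble with `f_lo`, `f_hi`.
#' @return Scalar area power.
#' @examples
#' fs <- 250
#' x <- sin(2 * pi * 8 * seq(0, 20, by = 1 / fs))
#' welch_band_power(x, fs, band("theta")) # ~ 0.5, the sine's variance
#' @export
welch_band_power <- function(x, fs, band, window_s = 4, overlap = 0.5) {
  check_band(band, fs)
  psd <- welch_psd(x, fs, window_s, overlap)
  df <- attr(psd, "df")
  sel <- psd$freq >= band$f_lo & psd$freq <= band$f_hi
  sum(psd$power[sel]) * df
}

#' Morlet wavelet spectrogram
#'
#' Time-frequency power via convolution with complex Morlet wavelets
#' (default 6 cycles, trading time against frequency resolution at theta).
#' The `time_avg` component is the time-averaged power per frequency, the
#' white-line summary conventionally drawn over LFP spectrograms.
#'
#' @inheritParams bandpass_filter
#' @param freqs Frequency grid in Hz, strictly inside (0, Nyquist).
#' @param n_cycles Wavelet width in cycles.
#' @param downsample Keep every `downsample`-th time point in the output.
#' @return An object of class `nc_spectrogram`: list with `times`, `freqs`,
#'   `power` (frequency x time matrix) and `time_avg`.
#' @export
morlet_spectrogram <- function(x, fs, freqs, n_cycles = 6, downsample = 1L) {
  stopifnot(all(freqs > 0), all(freqs < fs / 2))
  n <- length(x)
  keep <- seq(1L, n, by = max(1L, as.integer(downsample)))
  fx <- stats::fft(x)
  fgrid <- (seq_len(n) - 1L) / n * fs
  fgrid[fgrid > fs / 2] <- fgrid[fgrid > fs / 2] - fs # signed frequencies
  power <- matrix(0, nrow = length(freqs), ncol = length(keep))
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigma_t <- n_cycles / (2 * pi * f0)
    # Fourier transform of the (unit-energy-normalised) Morlet wavelet
    hw <- exp(-0.5 * ((fgrid - f0) * 2 * pi * sigma_t)^2) * 2
    conv <- stats::fft(fx * hw, inverse = TRUE) / n
    power[i, ] <- Mod(conv[keep])^2
  }
  out <- list(times = (keep - 1L) / fs, freqs = freqs, power = power,
              time_avg = rowMeans(power))
  class(out) <- "nc_spectrogram"
  out
}

#' Respiration cycle statistics
#'
#' Detects respiration cycles by peak-picking the 1-8 Hz band-passed chest
#' movement trace; per-cycle frequency is the reciprocal inter-peak
#' interval.
#'
#' @param piezo Respiration (piezo/chest movement) trace, arbitrary units.
#' @param fs Sampling rate in Hz.
#' @return List with `cycle_times` (peak times, s), `median_freq` (Hz) and
#'   `iqr` (two-element vector, Hz).
#' @export
respiration_stats <- function(piezo, fs) {
  if (length(piezo) < 5 * fs) {
    stop("need at least 5 s of respiration signal", call. = FALSE)
  }
  xf <- bandpass_filter(piezo, fs, nc_band("resp", 1, 8))
  thr <- 0.2 * stats::sd(xf)
  n <- length(xf)
  is_peak <- c(FALSE, xf[2:(n - 1)] > xf[1:(n - 2)] &
                 xf[2:(n - 1)] >= xf[3:n], FALSE) & xf > thr
  pk <- which(is_peak)
  # enforce a refractory distance of one eighth of a second (8 Hz upper edge)
  if (length(pk) > 1L) {
    min_dist <- round(fs / 8)
    keep <- pk[1L]
    for (p in pk[-1L]) if (p - keep[length(keep)] >= min_dist) keep <- c(keep, p)
    pk <- keep
  }
  if (length(pk) < 2L) stop("no respiration cycles detected", call. = FALSE)
  times <- (pk - 1L) / fs
  f <- 1 / diff(times)
  list(cycle_times = times,
       median_freq = stats::median(f),
       iqr = unname(stats::quantile(f, c(0.25, 0.75))))
}

# Anti-aliased decimation to a target LFP rate (integer factors only).
decimate_lfp <- function(x, fs, fs_target = 1000) {
  if (fs <= fs_target) return(list(x = x, fs = fs))
  q <- fs / fs_target
  if (abs(q - round(q)) > 1e-9) {
    stop("fs must be an integer multiple of the target rate", call. = FALSE)
  }
  q <- as.integer(round(q))
  bf <- signal::butter(6, (0.4 * fs_target) / (fs / 2), type = "low")
  xf <- as.numeric(signal::filtfilt(bf, x))
  list(x = xf[seq(1L, length(xf), by = q)], fs = fs_target)
}
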