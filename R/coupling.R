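#' Instantaneous phase of a band-limited component
#'
#' Phase of the analytic signal of the zero-phase band-filtered trace.
#' Convention: phase 0 at the oscillation peak, +/-pi at the trough.
#'
#' @inheritParams bandpass_filter
#' @return Phase series in (-pi, pi], same length as `x`.
#' @export
instantaneous_phase <- function(x, fs, band) {
  Arg(analytic_signal(bandpass_filter(x, fs, band)))
}

# Rayleigh test of circular uniformity (Zar's approximation of the p-value).
rayleigh_p <- function(n, R) {
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  min(1, max(0, p))
}

#' Spike-field phase locking (pairwise phase consistency)
#'
#' Samples the field phase at each spike time and quantifies locking by the
#' pairwise phase consistency (PPC), the average cosine of the phase
#' difference over all spike pairs,
#' `PPC = 2 / (N (N - 1)) * sum_{j<k} cos(theta_j - theta_k)`,
#' computed through the algebraically identical closed form
#' `(N R^2 - 1) / (N - 1)` where `R` is the resultant length. Unlike `R` (or
#' `R^2`), the PPC is unbiased in the number of spikes. Locking significance
#' is assessed by the Rayleigh test.
#'
#' @param times Spike times, s.
#' @param phase Phase series from [instantaneous_phase()], rad.
#' @param fs Sampling rate of `phase`, Hz.
#' @param restrict Optional event tibble; only spikes inside these intervals
#'   are used (e.g. theta locking restricted to detected bursts).
#' @param min_spikes_sig Minimum spike count for the significance call.
#' @param alpha Significance level of the Rayleigh test.
#' @return One-row tibble: `n`, `ppc`, `resultant` (R), `pref_phase` (rad),
#'   `p_rayleigh`, `significant`.
#' @export
phase_locking <- function(times, phase, fs, restrict = NULL,
                          min_spikes_sig = 20, alpha = 0.05) {
  if (!is.null(restrict)) times <- times[in_intervals(times, restrict)]
  n <- length(times)
  if (n < 2L) {
    stop("insufficient spikes: phase locking needs at least 2 spikes",
         call. = FALSE)
  }
  idx <- pmin(length(phase), pmax(1L, floor(times * fs) + 1L))
  th <- phase[idx]
  z <- mean(exp(1i * th))
  R <- Mod(z)
  ppc <- (n * R^2 - 1) / (n - 1)
  p <- rayleigh_p(n, R)
  tibble::tibble(
    n = n, ppc = ppc, resultant = R, pref_phase = wrap_pi(Arg(z)),
    p_rayleigh = p, significant = p < alpha && n >= min_spikes_sig)
}

#' Imaginary spectral coherence with surrogate threshold
#'
#' Imaginary part of the normalized Welch cross-spectrum,
#' `Im(Sxy / sqrt(Sxx Syy))`. The imaginary part is blind to zero-lag
#' (volume-conducted) synchrony: any instantaneous linear mixture of a
#' common source has imaginary coherence zero in expectation. A
#' per-frequency significance threshold is the 95th percentile of `|icoh|`
#' over surrogates in which `y` is circularly time-shifted by a random
#' offset of at least `min_shift_s`, which preserves each signal's spectrum
#' and autocorrelation while randomizing their phase alignment.
#'
#' @param x,y Signals of common length (>= 8 Welch windows).
#' @param fs Sampling rate, Hz.
#' @param window_s,overlap Welch segmentation.
#' @param n_surrogates Number of circular-shift surrogates (>= 100).
#' @param alpha Surrogate threshold tail probability.
#' @param min_shift_s Minimum circular shift, s.
#' @param bands Band tibble for band means (RR/theta/beta by default);
#'   band means are means of `|icoh|` over the band's frequencies.
#' @param seed Optional integer seed for the surrogate draws.
#' @return Object of class `nc_coherence`: list with `freq`, `icoh`,
#'   `threshold`, `band_means` (tibble `name`, `mean_abs_icoh`), and the
#'   call parameters.
#' @export
imaginary_coherence <- function(x, y, fs, window_s = 4, overlap = 0.5,
                                n_surrogates = 200, alpha = 0.05,
                                min_shift_s = 10, bands = NULL, seed = NULL) {
  stopifnot(length(x) == length(y), n_surrogates >= 100)
  n <- length(x)
  seg <- welch_segments(n, fs, window_s, overlap)
  k <- length(seg$starts)
  if (k < 8L) {
    stop("need at least 8 Welch windows for coherence", call. = FALSE)
  }
  nper <- seg$nper
  nf <- nper %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / nper
  tapered_ffts <- function(v) {
    vapply(seg$starts, function(s) {
      vs <- v[s:(s + nper - 1L)]
      stats::fft((vs - mean(vs)) * seg$win)[seq_len(nf)]
    }, complex(nf))
  }
  fx <- tapered_ffts(x) # nf x k
  sxx <- rowMeans(Mod(fx)^2)
  icoh_vs <- function(yv) {
    fy <- tapered_ffts(yv)
    Im(rowMeans(fx * Conj(fy)) / sqrt(sxx * rowMeans(Mod(fy)^2)))
  }
  icoh <- icoh_vs(y)
  min_shift <- round(min_shift_s * fs)
  if (n - min_shift <= min_shift) {
    stop("signal too short for ", min_shift_s, " s circular shifts",
         call. = FALSE)
  }
  sur <- with_seed(seed, {
    shifts <- sample(seq(min_shift, n - min_shift), n_surrogates,
                     replace = TRUE)
    vapply(shifts, function(s) {
      abs(icoh_vs(c(y[(s + 1L):n], y[1L:s])))
    }, numeric(nf))
  })
  threshold <- apply(sur, 1L, mc_threshold, alpha = alpha)
  w <- list(freq = freq)
  bands <- bands %||% nc_bands()[nc_bands()$name %in%
                                   c("rr", "theta", "beta"), ]
  band_means <- bands |>
    dplyr::rowwise() |>
    dplyr::summarise(name = .data$name, mean_abs_icoh = mean(
      abs(icoh[w$freq >= .data$f_lo & w$freq <= .data$f_hi])),
      .groups = "drop")
  structure(list(freq = w$freq, icoh = icoh, threshold = threshold,
                 band_means = band_means, window_s = window_s,
                 n_surrogates = n_surrogates, alpha = alpha),
            class = "nc_coherence")
}

#' @export
print.nc_coherence <- function(x, ...) {
  cat("<nc_coherence> ", length(x$freq), " frequencies, ",
      x$n_surrogates, " surrogates\n", sep = "")
  print(x$band_means)
  invisible(x)
}

#' Circular histogram of instantaneous phase differences
#'
#' Histogram of `dphi = phase(x) - phase(y)` in a band, with the circular
#' mean and resultant length. A positive circular mean at the band center
#' means `x` leads `y`.
#'
#' @inheritParams imaginary_coherence
#' @param band Band tibble.
#' @param restrict Optional event tibble restricting the samples used
#'   (theta phase lags are conventionally restricted to detected bursts).
#' @param n_bins Number of histogram bins over (-pi, pi].
#' @return List of class `nc_phase_lag`: `breaks`, `counts`, `circ_mean`,
#'   `resultant`, `n`.
#' @export
phase_lag_histogram <- function(x, y, fs, band, restrict = NULL,
                                n_bins = 24) {
  dphi <- wrap_pi(instantaneous_phase(x, fs, band) -
                    instantaneous_phase(y, fs, band))
  if (!is.null(restrict)) {
    t <- (seq_along(x) - 1L) / fs
    dphi <- dphi[in_intervals(t, restrict)]
  }
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  counts <- graphics::hist(dphi, breaks = breaks, plot = FALSE)$counts
  z <- mean(exp(1i * dphi))
  structure(list(breaks = breaks, counts = counts,
                 circ_mean = wrap_pi(Arg(z)), resultant = Mod(z),
                 n = length(dphi)),
            class = "nc_phase_lag")
}

#' Maximal band-limited cross-correlation
#'
#' Normalized cross-correlation of the band-filtered signals over lags up to
#' `max_lag_ms`; returns the peak and its lag. A peak at lag `+k` ms means
#' the correlation is maximal between `x` at time `t` and `y` at `t + k`,
#' i.e. `y` is a delayed copy when `k > 0`.
#'
#' @inheritParams phase_lag_histogram
#' @param max_lag_ms Maximum lag scanned, ms.
#' @return One-row tibble: `max_corr`, `lag_ms`.
#' @export
lfp_max_crosscorr <- function(x, y, fs, band, max_lag_ms = 100) {
  xf <- bandpass_filter(x, fs, band)
  yf <- bandpass_filter(y, fs, band)
  xf <- xf - mean(xf)
  yf <- yf - mean(yf)
  maxlag <- round(max_lag_ms / 1000 * fs)
  n <- length(xf)
  denom <- sqrt(sum(xf^2) * sum(yf^2))
  lags <- -maxlag:maxlag
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      sum(xf[1:(n - l)] * yf[(1 + l):n])
    } else {
      sum(xf[(1 - l):n] * yf[1:(n + l)])
    }
  }, numeric(1)) / denom
  i <- which.max(r)
  tibble::tibble(max_corr = r[i], lag_ms = lags[i] / fs * 1000)
}

#' Standardized spike-spike cross-covariance
#'
#' Lag-resolved excess coincidence of two spike trains: the 1 ms-binned
#' cross-correlogram over +/-`max_lag_ms`, minus its expectation under
#' independence, divided by the standard deviation under independence, then
#' smoothed with a narrow Gaussian kernel. Following the developmental
#' literature's convention, lag is `t_a - t_b`: a *negative* peak lag means
#' train `a` (e.g. OB) leads/drives train `b` (e.g. LEC). Significance uses
#' a global band: the `1 - alpha` quantile of the per-surrogate maximum
#' `|z|` under interval jitter of the second train (each spike re-drawn
#' uniformly within its fixed window of width `2 * jitter_ms`). Interval
#' jitter makes the observed correlogram exchangeable with the surrogates
#' under the null of no timing structure finer than the jitter window, so
#' the band controls the family-wise error over lags at level `alpha`.
#'
#' @param a,b Spike time vectors, s (both must exceed `rate_min`).
#' @param duration Common observation span, s.
#' @param binsize_ms Correlogram bin, ms.
#' @param max_lag_ms Maximum lag, ms.
#' @param smooth_sd_ms Gaussian smoothing SD, ms (kernel truncated at
#'   +/-5 ms by default width).
#' @param n_surrogates Jitter surrogates for the significance band.
#' @param jitter_ms Surrogate jitter half-width, ms.
#' @param alpha Tail probability of the global band.
#' @param rate_min Inclusion threshold, Hz (strict).
#' @param seed Optional integer seed.
#' @return Object of class `nc_crosscov`: list with `lags_ms`, `z`
#'   (smoothed standardized cross-covariance), `threshold`, `sig_lags_ms`,
#'   `n_a`, `n_b`.
#' @export
spike_crosscovariance <- function(a, b, duration, binsize_ms = 1,
                                  max_lag_ms = 50, smooth_sd_ms = 2,
                                  n_surrogates = 200, jitter_ms = 25,
                                  alpha = 0.05, rate_min = 0.05,
                                  seed = NULL) {
  for (nm in c("a", "b")) {
    tr <- get(nm)
    if (length(tr) / duration <= rate_min) {
      stop("train '", nm, "' fails the rate filter (<= ", rate_min, " Hz)",
           call. = FALSE)
    }
  }
  bs <- binsize_ms / 1000
  nbins_lag <- round(max_lag_ms / binsize_ms)
  lags <- (-nbins_lag):nbins_lag
  n_bins_total <- round(duration / bs)
  n_a <- length(a)
  n_b <- length(b)
  mu <- n_a * n_b / n_bins_total
  sigma <- sqrt(mu * (1 - n_a / n_bins_total) * (1 - n_b / n_bins_total))

  # Gaussian smoothing kernel on the standardized correlogram
  ker_half <- max(1L, round(5 / binsize_ms))
  ker <- stats::dnorm((-ker_half):ker_half, sd = smooth_sd_ms / binsize_ms)
  ker <- ker / sum(ker)
  smooth_z <- function(z) {
    as.numeric(stats::filter(c(rep(z[1L], ker_half), z,
                               rep(z[length(z)], ker_half)),
                             ker, sides = 2))[ker_half + seq_along(z)]
  }

  # All spike-pair lag differences within reach of the window after jitter
  reach <- (max_lag_ms + 2 * jitter_ms + binsize_ms) / 1000
  pair_d <- list()
  pair_bid <- list()
  j0 <- 1L
  for (i in seq_along(a)) {
    while (j0 <= n_b && b[j0] < a[i] - reach) j0 <- j0 + 1L
    j <- j0
    while (j <= n_b && b[j] <= a[i] + reach) j <- j + 1L
    if (j > j0) {
      pair_d[[length(pair_d) + 1L]] <- a[i] - b[j0:(j - 1L)]
      pair_bid[[length(pair_bid) + 1L]] <- j0:(j - 1L)
    }
  }
  d <- unlist(pair_d) %||% numeric(0)
  bid <- unlist(pair_bid) %||% integer(0)

  count_lags <- function(dd) {
    k <- round(dd / bs)
    k <- k[abs(k) <= nbins_lag]
    tabulate(k + nbins_lag + 1L, nbins = 2L * nbins_lag + 1L)
  }
  z <- smooth_z((count_lags(d) - mu) / sigma)

  jw <- 2 * jitter_ms / 1000 # jitter partition width
  b_cell <- floor(b / jw)
  sur_max <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      b_new <- (b_cell + stats::runif(n_b)) * jw
      zs <- smooth_z((count_lags(d + b[bid] - b_new[bid]) - mu) / sigma)
      max(abs(zs))
    }, numeric(1))
  })
  threshold <- mc_threshold(sur_max, alpha)
  sig <- lags[abs(z) > threshold] * binsize_ms
  structure(list(lags_ms = lags * binsize_ms, z = z, threshold = threshold,
                 sig_lags_ms = sig, n_a = n_a, n_b = n_b,
                 binsize_ms = binsize_ms),
            class = "nc_crosscov")
}

#' @export
print.nc_crosscov <- function(x, ...) {
  cat("<nc_crosscov> lags +/-", max(x$lags_ms), "ms, threshold |z| >",
      round(x$threshold, 2), "\n")
  if (length(x$sig_lags_ms)) {
    pk <- x$sig_lags_ms[which.max(abs(x$z[x$lags_ms %in% x$sig_lags_ms]))]
    cat("  significant lags:", paste(x$sig_lags_ms, collapse = ", "),
        "ms; peak at", pk, "ms\n")
  } else {
    cat("  no significant lags\n")
  }
  invisible(x)
}

#' Mono/poly/zero-lag connectivity classification
#'
#' Classifies a cross-covariance result by the lag of its largest
#' significant peak: within +/-1 ms is undirected zero-lag coupling
#' (common input), a peak inside the monosynaptic window (1-10 ms) or the
#' polysynaptic window (10-50 ms) is directed with direction given by the
#' lag sign (negative lag: `a` drives `b`).
#'
#' @param res An `nc_crosscov` object.
#' @param mono_lag,poly_lag Two-element ms windows.
#' @return One of `"none"`, `"undirected_zero_lag"`, `"mono_ab"`,
#'   `"mono_ba"`, `"poly_ab"`, `"poly_ba"`.
#' @export
classify_connectivity <- function(res, mono_lag = c(1, 10),
                                  poly_lag = c(10, 50)) {
  stopifnot(inherits(res, "nc_crosscov"), mono_lag[2] <= poly_lag[1])
  if (length(res$sig_lags_ms) == 0L) return("none")
  sig_idx <- which(res$lags_ms %in% res$sig_lags_ms)
  peak <- res$lags_ms[sig_idx[which.max(abs(res$z[sig_idx]))]]
  al <- abs(peak)
  if (al <= mono_lag[1]) return("undirected_zero_lag")
  dir <- if (peak < 0) "ab" else "ba"
  if (al <= mono_lag[2]) return(paste0("mono_", dir))
  if (al <= poly_lag[2]) return(paste0("poly_", dir))
  "none"
}
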