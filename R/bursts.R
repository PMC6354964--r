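#' Detect discontinuous oscillatory (theta) bursts
#'
#' Detects spindle-shaped oscillatory events on one LFP channel. The signal
#' is band-passed (4-30 Hz by default), its analytic-signal envelope is
#' smoothed with a 200 ms moving average, and event cores are marked where
#' the envelope exceeds `mean + thresh_sd * sd`. Because the events are
#' amplitude-tapered and can occupy a substantial fraction of the recording,
#' event extent is then measured by extending each core outward to where the
#' envelope falls back to the noise floor (the median envelope outside the
#' padded cores). Events closer than `merge_gap_s` are merged and events
#' shorter than `min_dur_s` discarded. The threshold is data-derived, so
#' detection is invariant to rescaling the signal.
#'
#' @param x LFP signal, uV.
#' @param fs Sampling rate, Hz.
#' @param params [analysis_params()]; the detector settings used are
#'   `burst_env_band`, `burst_smooth_s`, `burst_thresh_sd`,
#'   `burst_min_dur_s`, `burst_merge_gap_s`, `burst_guard_s`.
#' @return Tibble with one row per event: `start`, `stop`, `duration` (s),
#'   `peak_amp` (uV, peak of the smoothed envelope) and `band_power`
#'   (uV^2, mean square of the 4-12 Hz component inside the event).
#' @export
detect_theta_bursts <- function(x, fs, params = analysis_params()) {
  p <- params
  smooth_n <- round(p$burst_smooth_s * fs)
  if (length(x) <= smooth_n) {
    stop("signal shorter than the envelope smoothing window", call. = FALSE)
  }
  empty <- tibble::tibble(start = numeric(0), stop = numeric(0),
                          duration = numeric(0), peak_amp = numeric(0),
                          band_power = numeric(0))
  if (all(x == 0)) return(empty)
  xf <- bandpass_filter(x, fs, p$burst_env_band)
  env <- moving_average(Mod(analytic_signal(xf)), smooth_n)
  core_thr <- mean(env) + p$burst_thresh_sd * stats::sd(env)
  cores <- logical_runs(env > core_thr)
  # noise excursions above the core threshold are brief (the envelope is
  # smoothed over 200 ms); genuine oscillatory events hold it for much
  # longer, so short cores are discarded before boundary extension
  core_min <- round((p$burst_core_min_s %||% 0.4) * fs)
  cores <- cores[cores[, 2L] - cores[, 1L] + 1L >= core_min, , drop = FALSE]
  if (nrow(cores) == 0L) return(empty)

  # noise floor from outside the cores (padded), robust to burst occupancy
  pad <- round(1 * fs)
  outside <- rep(TRUE, length(env))
  for (i in seq_len(nrow(cores))) {
    outside[max(1L, cores[i, 1L] - pad):min(length(env),
                                            cores[i, 2L] + pad)] <- FALSE
  }
  floor_thr <- if (any(outside)) {
    stats::median(env[outside])
  } else {
    stats::quantile(env, 0.25, names = FALSE)
  }
  floor_thr <- min(floor_thr, core_thr) # degenerate signals

  above <- env >= floor_thr
  runs <- logical_runs(above)
  # map each core to the floor-level run containing it
  hit <- unique(findInterval(cores[, 1L], runs[, 1L]))
  ev <- merge_intervals((runs[hit, 1L] - 1L) / fs, runs[hit, 2L] / fs,
                        gap = p$burst_merge_gap_s)
  ev <- ev[ev$stop - ev$start >= p$burst_min_dur_s, ]
  if (nrow(ev) == 0L) return(empty)

  theta <- bandpass_filter(x, fs, band("theta"))
  t <- (seq_along(x) - 1L) / fs
  ev$duration <- ev$stop - ev$start
  ev$peak_amp <- NA_real_
  ev$band_power <- NA_real_
  for (i in seq_len(nrow(ev))) {
    sel <- t >= ev$start[i] & t < ev$stop[i]
    ev$peak_amp[i] <- max(env[sel])
    ev$band_power[i] <- mean(theta[sel]^2)
  }
  ev[, c("start", "stop", "duration", "peak_amp", "band_power")]
}

#' Population summary of detected bursts
#'
#' @param events Event tibble from [detect_theta_bursts()].
#' @param x The signal the events were detected on.
#' @param fs Sampling rate, Hz.
#' @param band Band for the in/out power ratio (theta by default).
#' @param guard_s Guard time excluded around each event when estimating
#'   non-burst power, to avoid envelope bleed.
#' @return One-row tibble: `occurrence` (events/min), `duration` (median s),
#'   `amplitude` (median peak uV), `relative_power` (in-burst / non-burst
#'   band area power; `NA` when non-burst power is zero) and
#'   `discontinuity` (fraction of time inside events).
#' @export
burst_summary <- function(events, x, fs, band = NULL, guard_s = 0.5) {
  band <- band %||% nc_bands()[nc_bands()$name == "theta", ]
  total_s <- length(x) / fs
  n_ev <- nrow(events)
  t <- (seq_along(x) - 1L) / fs
  xf <- bandpass_filter(x, fs, band)
  inside <- in_intervals(t, events)
  guarded <- if (n_ev > 0L) {
    g <- events
    g$start <- pmax(0, g$start - guard_s)
    g$stop <- g$stop + guard_s
    in_intervals(t, merge_intervals(g$start, g$stop))
  } else {
    inside
  }
  p_in <- if (any(inside)) mean(xf[inside]^2) else NA_real_
  p_out <- if (any(!guarded)) mean(xf[!guarded]^2) else NA_real_
  rel <- if (is.na(p_out) || p_out == 0) NA_real_ else p_in / p_out
  tibble::tibble(
    occurrence = n_ev / (total_s / 60),
    duration = if (n_ev) stats::median(events$stop - events$start) else NA_real_,
    amplitude = if (n_ev && "peak_amp" %in% names(events)) {
      stats::median(events$peak_amp)
    } else {
      NA_real_
    },
    relative_power = rel,
    discontinuity = sum(events$stop - events$start) / total_s)
}

#' Cross-region burst co-occurrence
#'
#' An event in one region co-occurs with the other region's bursts when some
#' event there overlaps it by at least `overlap_frac` of the *shorter*
#' event's duration. Because the reference set is ambiguous, the fraction is
#' reported over A's events, over B's events and over their union.
#'
#' @param a,b Event tibbles (`start`, `stop`).
#' @param overlap_frac Required overlap fraction in (0, 1].
#' @return List with `frac_a`, `frac_b`, `frac_union` and the per-event
#'   logical flags `a_flag`, `b_flag`.
#' @export
burst_cooccurrence <- function(a, b, overlap_frac = 0.6) {
  stopifnot(overlap_frac > 0, overlap_frac <= 1)
  flag <- function(x, y) {
    if (nrow(x) == 0L) return(logical(0))
    vapply(seq_len(nrow(x)), function(i) {
      if (nrow(y) == 0L) return(FALSE)
      ov <- pmin(x$stop[i], y$stop) - pmax(x$start[i], y$start)
      shorter <- pmin(x$stop[i] - x$start[i], y$stop - y$start)
      any(ov >= overlap_frac * shorter & shorter > 0)
    }, logical(1))
  }
  a_flag <- flag(a, b)
  b_flag <- flag(b, a)
  n <- length(a_flag) + length(b_flag)
  list(
    frac_a = if (length(a_flag)) mean(a_flag) else NA_real_,
    frac_b = if (length(b_flag)) mean(b_flag) else NA_real_,
    frac_union = if (n) sum(a_flag, b_flag) / n else NA_real_,
    a_flag = a_flag, b_flag = b_flag)
}
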