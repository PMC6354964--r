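#' Synthetic session configuration
#'
#' Parameters of the two-region synthetic generator. Defaults are anchored
#' to the descriptive statistics of neonatal olfactory-bulb recordings:
#' continuous respiration-related rhythm at 2.37 Hz, discontinuous
#' spindle-shaped theta bursts at ~4.7 events/min lasting ~4.5 s with
#' ~75 uV envelope peak, an entorhinal channel receiving a lagged,
#' attenuated copy (amplitude ratio 0.76) of the bulb oscillations, units
#' firing preferentially inside bursts and at the oscillation trough, and
#' driven downstream units copying source spikes at mono- (5 ms) or
#' polysynaptic (36 ms) delays. Background is 1/f noise; between bursts the
#' neonatal LFP is close to quiescent, hence the low 4 uV rms floor.
#'
#' @param duration_s Session length in seconds.
#' @param fs Sampling rate in Hz.
#' @param rr_freq Respiration-related rhythm frequency (Hz); the realised
#'   frequency drifts slowly by +/-10%.
#' @param rr_amp RR amplitude in the source (OB) channel, uV.
#' @param burst_rate Theta burst rate, events/min.
#' @param burst_dur_mean,burst_dur_sd Burst duration distribution
#'   (truncated normal, >= 0.5 s), seconds.
#' @param burst_center_freq Burst carrier frequency, Hz.
#' @param burst_amp Burst envelope peak amplitude, uV.
#' @param lfp_lag_ms Field lag of the downstream (LEC) channel, ms.
#' @param amp_ratio Downstream/source amplitude ratio (0 < ratio <= 1).
#' @param noise_exponent 1/f noise exponent.
#' @param noise_rms Background noise rms, uV.
#' @param units Tibble describing the units: `unit_id`, `region`,
#'   `base_rate` (Hz), `burst_gain`, `kappa`, `mu` (rad), `drive`
#'   (`"none"`, `"mono"`, `"poly"`), `drive_delay_ms`, `drive_prob`,
#'   `source` (unit id copied by driven units).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   session.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 600, fs = 1000, rr_freq = 2.37,
                         rr_amp = 17, burst_rate = 4.7, burst_dur_mean = 4.5,
                         burst_dur_sd = 1.5, burst_center_freq = 8,
                         burst_amp = 75, lfp_lag_ms = 15, amp_ratio = 0.76,
                         noise_exponent = 1, noise_rms = 4,
                         units = default_units(), seed = 1L) {
  stopifnot(duration_s > 0, fs >= 200, rr_freq > 0, burst_rate >= 0,
            amp_ratio > 0, amp_ratio <= 1, noise_rms >= 0)
  if (nrow(units) > 0L) {
    stopifnot(all(units$base_rate >= 0), all(units$kappa >= 0),
              all(units$drive_prob >= 0 & units$drive_prob <= 1))
  }
  structure(
    list(duration_s = duration_s, fs = fs, rr_freq = rr_freq, rr_amp = rr_amp,
         burst_rate = burst_rate, burst_dur_mean = burst_dur_mean,
         burst_dur_sd = burst_dur_sd, burst_center_freq = burst_center_freq,
         burst_amp = burst_amp, lfp_lag_ms = lfp_lag_ms,
         amp_ratio = amp_ratio, noise_exponent = noise_exponent,
         noise_rms = noise_rms, units = units, seed = seed),
    class = "synth_config")
}

#' @rdname synth_config
#' @export
default_units <- function() {
  tibble::tibble(
    unit_id = c("ob_u1", "ob_u2", "ob_u3", "lec_mono", "lec_poly", "lec_u3"),
    region = c("OB", "OB", "OB", "LEC", "LEC", "LEC"),
    base_rate = c(1.0, 0.8, 0.5, 0.3, 0.3, 0.2),
    burst_gain = c(3, 3, 3, 4, 4, 4),
    kappa = c(1, 1, 1, 0.8, 0.8, 0.8),
    mu = rep(pi, 6), # firing at the oscillation trough
    drive = c("none", "none", "none", "mono", "poly", "none"),
    drive_delay_ms = c(NA, NA, NA, 5, 36, NA),
    drive_prob = c(0, 0, 0, 0.4, 0.4, 0),
    source = c(NA, NA, NA, "ob_u1", "ob_u2", NA))
}

# 1/f^a noise by spectral shaping of white noise, scaled to a target rms.
one_over_f_noise <- function(n, fs, exponent = 1, rms = 1) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  fw <- stats::fft(w)
  f <- (seq_len(n) - 1L) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- c(0, 1 / pmax(f[-1L], f[2L])^(exponent / 2))
  x <- Re(stats::fft(fw * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Poisson burst-event skeleton
#'
#' Draws Poisson event starts with truncated-normal durations (>= 0.5 s) and
#' merges overlapping events, so the returned intervals never overlap. The
#' number of raw (pre-merge) events is attached as attribute `raw_count`.
#'
#' @param rate Events per minute.
#' @param dur_mean,dur_sd Duration distribution, seconds.
#' @param duration_s Total time span, seconds.
#' @param seed Optional integer seed.
#' @return Tibble of `start`, `stop` intervals, sorted.
#' @export
generate_burst_train <- function(rate, dur_mean, dur_sd, duration_s,
                                 seed = NULL) {
  stopifnot(rate >= 0)
  if (rate / 60 * dur_mean >= 1) {
    stop("burst rate x duration implies full occupancy; events cannot be ",
         "placed without overlap", call. = FALSE)
  }
  with_seed(seed, {
    n <- stats::rpois(1L, rate / 60 * duration_s)
    if (n == 0L) {
      out <- tibble::tibble(start = numeric(0), stop = numeric(0))
      attr(out, "raw_count") <- 0L
      return(out)
    }
    starts <- sort(stats::runif(n, 0, duration_s))
    durs <- stats::rnorm(n, dur_mean, dur_sd)
    while (any(durs < 0.5)) { # truncation at 0.5 s by resampling
      bad <- durs < 0.5
      durs[bad] <- stats::rnorm(sum(bad), dur_mean, dur_sd)
    }
    stops <- pmin(starts + durs, duration_s)
    out <- merge_intervals(starts, stops)
    attr(out, "raw_count") <- n
    out
  })
}

# Mean acceptance probability of von Mises thinning, exp(-k) I0(k); the
# generator divides the base rate by this so the requested rate is realised
# for any concentration.
vm_thinning_correction <- function(kappa) {
  exp(-kappa) * besselI(kappa, 0)
}

#' Phase-locked spike train by von Mises thinning
#'
#' Thins a homogeneous Poisson process with acceptance probability
#' `exp(kappa * (cos(phase - mu) - 1))` at the instantaneous phase, which
#' yields spike phases distributed as von Mises(mu, kappa). The base rate is
#' divided by the mean acceptance `exp(-kappa) I0(kappa)` so that the
#' realised mean rate matches `rate` for every concentration.
#'
#' @param phase Instantaneous phase series (rad), sampled at `fs`.
#' @param fs Sampling rate of `phase`, Hz.
#' @param rate Target mean firing rate, Hz.
#' @param kappa von Mises concentration (>= 0; 0 = no locking).
#' @param mu Preferred phase, rad.
#' @param duration_s Train length, seconds.
#' @param seed Optional integer seed.
#' @return Strictly increasing spike times in seconds.
#' @export
generate_locked_spike_train <- function(phase, fs, rate, kappa = 0, mu = 0,
                                        duration_s = length(phase) / fs,
                                        seed = NULL) {
  stopifnot(kappa >= 0, rate >= 0)
  if (rate == 0) return(numeric(0))
  with_seed(seed, {
    base <- rate / vm_thinning_correction(kappa)
    n <- stats::rpois(1L, base * duration_s)
    t <- sort(stats::runif(n, 0, duration_s))
    idx <- pmin(length(phase), floor(t * fs) + 1L)
    acc <- exp(kappa * (cos(phase[idx] - mu) - 1))
    keep <- stats::runif(n) < acc
    unique(t[keep])
  })
}

#' Generate a synthetic two-region session
#'
#' Builds a recording session with the statistical structure assumed by the
#' analyses in this package: source (OB) LFP = 1/f noise + slowly drifting
#' respiration-related sinusoid + Hann-enveloped theta bursts at Poisson
#' times; downstream (LEC) LFP = lagged, attenuated copy of the oscillatory
#' components on independent noise; a respiration trace phase-locked to the
#' RR component; units firing as inhomogeneous point processes gated by
#' burst state and von Mises phase preference; and driven downstream units
#' copying source spikes at a configured delay with <= 0.5 ms jitter.
#' Ground truth (burst intervals per region, per-unit locking parameters and
#' drive delays, RR frequency) is attached for parameter-recovery tests.
#'
#' @param config A [synth_config()].
#' @return A `recording_session` with `$truth`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- round(cf$duration_s * cf$fs)
    t <- (seq_len(n) - 1L) / cf$fs
    # RR with slow +/-10% frequency drift (period 60 s)
    f_inst <- cf$rr_freq * (1 + 0.1 * sin(2 * pi * t / 60))
    phi_rr <- 2 * pi * cumsum(f_inst) / cf$fs
    rr_wave <- cf$rr_amp * cos(phi_rr)

    bursts <- generate_burst_train(cf$burst_rate, cf$burst_dur_mean,
                                   cf$burst_dur_sd, cf$duration_s)
    burst_wave <- numeric(n)
    phi_theta <- numeric(n) # carrier phase inside bursts, 0 elsewhere
    if (nrow(bursts) > 0L) {
      for (i in seq_len(nrow(bursts))) {
        i0 <- floor(bursts$start[i] * cf$fs) + 1L
        i1 <- min(n, ceiling(bursts$stop[i] * cf$fs))
        m <- i1 - i0 + 1L
        hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L))
        ph0 <- stats::runif(1L, 0, 2 * pi)
        ph <- 2 * pi * cf$burst_center_freq * (t[i0:i1] - t[i0]) + ph0
        burst_wave[i0:i1] <- burst_wave[i0:i1] + cf$burst_amp * hann * cos(ph)
        phi_theta[i0:i1] <- ph
      }
    }
    lag <- round(cf$lfp_lag_ms / 1000 * cf$fs)
    shift <- function(x) c(numeric(lag), x[seq_len(n - lag)])
    osc_ob <- rr_wave + burst_wave
    lfp_ob <- osc_ob + one_over_f_noise(n, cf$fs, cf$noise_exponent,
                                        cf$noise_rms)
    lfp_lec <- cf$amp_ratio * shift(osc_ob) +
      one_over_f_noise(n, cf$fs, cf$noise_exponent, cf$noise_rms)

    in_burst_ob <- in_intervals(t, bursts)
    bursts_lec <- bursts
    if (nrow(bursts) > 0L) {
      bursts_lec$start <- pmin(bursts$start + lag / cf$fs, cf$duration_s)
      bursts_lec$stop <- pmin(bursts$stop + lag / cf$fs, cf$duration_s)
    }
    in_burst_lec <- in_intervals(t, bursts_lec)
    phi_rr_lec <- c(phi_rr[seq_len(lag)], phi_rr[seq_len(n - lag)])
    phi_theta_lec <- c(numeric(lag), phi_theta[seq_len(n - lag)])

    # Per-unit modulation phase: RR phase outside bursts, carrier phase inside
    spikes <- empty_spikes()
    times_by_unit <- list()
    for (i in seq_len(nrow(cf$units))) {
      u <- cf$units[i, ]
      if (u$region == "OB") {
        phase_u <- ifelse(in_burst_ob, phi_theta, phi_rr)
        in_burst <- in_burst_ob
      } else {
        phase_u <- ifelse(in_burst_lec, phi_theta_lec, phi_rr_lec)
        in_burst <- in_burst_lec
      }
      gain <- ifelse(in_burst, u$burst_gain, 1)
      base <- u$base_rate / vm_thinning_correction(u$kappa)
      rate_max <- base * max(gain)
      m <- stats::rpois(1L, rate_max * cf$duration_s)
      cand <- sort(stats::runif(m, 0, cf$duration_s))
      idx <- pmin(n, floor(cand * cf$fs) + 1L)
      acc <- (gain[idx] / max(gain)) *
        exp(u$kappa * (cos(phase_u[idx] - u$mu) - 1))
      own <- cand[stats::runif(m) < acc]
      drv <- numeric(0)
      if (!is.na(u$source) && u$drive != "none" && u$drive_prob > 0) {
        src <- times_by_unit[[u$source]]
        if (!is.null(src) && length(src) > 0L) {
          sel <- src[stats::runif(length(src)) < u$drive_prob]
          jit <- stats::runif(length(sel), -0.5, 0.5) / 1000
          drv <- sel + u$drive_delay_ms / 1000 + jit
        }
      }
      all_t <- sort(unique(c(own, drv)))
      all_t <- all_t[all_t >= 0 & all_t < cf$duration_s]
      times_by_unit[[u$unit_id]] <- all_t
      spikes <- dplyr::bind_rows(spikes, tibble::tibble(
        unit_id = u$unit_id, region = u$region, time = all_t))
    }

    respiration <- list(x = cos(phi_rr - pi / 2), fs = cf$fs)
    truth <- list(
      bursts = dplyr::bind_rows(
        tibble::tibble(region = "OB", start = bursts$start,
                       stop = bursts$stop),
        tibble::tibble(region = "LEC", start = bursts_lec$start,
                       stop = bursts_lec$stop)),
      units = cf$units[, c("unit_id", "region", "kappa", "mu", "drive",
                           "drive_delay_ms", "drive_prob", "source")],
      rr_freq = cf$rr_freq)

    recording_session(
      session_id = sprintf("synth-seed%d", cf$seed),
      fs_lfp = cf$fs,
      lfp = cbind(ob1 = lfp_ob, lec1 = lfp_lec),
      channels = tibble::tibble(channel = c("ob1", "lec1"),
                                region = c("OB", "LEC"),
                                layer = c("MCL", "II/III")),
      spikes = spikes, respiration = respiration, truth = truth)
  })
}
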