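# Independent oracles and fixture builders used across the suite.

# O(N^2) brute-force pairwise phase consistency (definition form).
ppc_bruteforce <- function(theta) {
  n <- length(theta)
  s <- 0
  for (j in 1:(n - 1)) {
    s <- s + sum(cos(theta[j] - theta[(j + 1):n]))
  }
  2 * s / (n * (n - 1))
}

# von Mises draws by thinning uniform proposals (independent of the
# package's spike-train generator).
rvonmises <- function(n, mu, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    prop <- stats::runif(2 * n, -pi, pi)
    acc <- stats::runif(2 * n) < exp(kappa * (cos(prop - mu) - 1))
    out <- c(out, prop[acc])
  }
  out[seq_len(n)]
}

# Closed-form population PPC of a von Mises distribution.
ppc_vonmises <- function(kappa) (besselI(kappa, 1) / besselI(kappa, 0))^2

# Pink-noise fixture: spindle-shaped events added on a 1/f background.
make_spindle_signal <- function(fs, dur, starts, spindle_dur, amp,
                                noise_rms = 20, f0 = 8) {
  x <- neocoupling:::one_over_f_noise(dur * fs, fs, 1, noise_rms)
  t <- (seq_len(dur * fs) - 1) / fs
  for (s0 in starts) {
    sel <- t >= s0 & t < s0 + spindle_dur
    m <- sum(sel)
    x[sel] <- x[sel] +
      amp * (0.5 - 0.5 * cos(2 * pi * seq_len(m) / m)) * sin(2 * pi * f0 * t[sel])
  }
  x
}

# Minimal two-channel session with supplied spikes, for pipeline tests.
make_tiny_session <- function(dur = 60, fs = 1000, spikes = NULL, seed = 1) {
  cfg <- synth_config(duration_s = dur, fs = fs, seed = seed,
                      units = default_units()[c(1, 4), ])
  s <- generate_session(cfg)
  if (!is.null(spikes)) s$spikes <- spikes
  s
}
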