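test_that("burst skeleton matches its Poisson and merged-cluster oracles", {
  # zero rate
  expect_equal(nrow(generate_burst_train(0, 4.5, 1.5, 600, seed = 1)), 0)
  # raw (pre-merge) counts follow the Poisson expectation; the returned
  # merged intervals follow an independent Monte-Carlo merge oracle
  raw <- numeric(100)
  merged <- numeric(100)
  for (i in 1:100) {
    b <- generate_burst_train(5, 4.5, 1.5, 600, seed = i)
    raw[i] <- attr(b, "raw_count")
    merged[i] <- nrow(b)
    expect_true(nrow(b) < 2 || all(b$start[-1] >= b$stop[-nrow(b)]))
  }
  expect_lt(abs(mean(raw) - 50), 2)
  oracle <- replicate(300, { # independent simulation of the merge process
    n <- rpois(1, 50)
    if (n == 0) return(0)
    st <- sort(runif(n, 0, 600))
    du <- rnorm(n, 4.5, 1.5)
    while (any(du < 0.5)) du[du < 0.5] <- rnorm(sum(du < 0.5), 4.5, 1.5)
    sp <- cummax(pmin(st + du, 600))
    1 + sum(st[-1] > sp[-n])
  })
  expect_lt(abs(mean(merged) - mean(oracle)),
            3 * sd(oracle) / sqrt(300) + 3 * sd(merged) / sqrt(100))
})

test_that("overfull burst configurations are rejected", {
  expect_error(generate_burst_train(20, 4.5, 0.5, 600), "occupancy")
})

test_that("von Mises thinning yields the requested rate and locking", {
  fs <- 1000
  phase <- ((seq_len(600 * fs) - 1) / fs * 2 * pi * 3) %% (2 * pi) - pi
  # kappa = 0: uniform phases, calibrated rate, PPC ~ 0
  tr0 <- generate_locked_spike_train(phase, fs, rate = 10, kappa = 0,
                                     duration_s = 600, seed = 2)
  expect_lt(abs(length(tr0) / 600 - 10) / 10, 0.05)
  th0 <- phase[floor(tr0 * fs) + 1]
  n0 <- 5000
  expect_lt(abs((n0 * Mod(mean(exp(1i * th0[1:n0])))^2 - 1) / (n0 - 1)),
            0.01)
  # kappa > 0: rate correction holds, locking near the closed form
  tr2 <- generate_locked_spike_train(phase, fs, rate = 5, kappa = 2,
                                     mu = pi, duration_s = 600, seed = 3)
  expect_lt(abs(length(tr2) / 600 - 5) / 5, 0.05)
  pl <- phase_locking(tr2, phase, fs)
  expect_lt(abs(pl$ppc - ppc_vonmises(2)), 0.05)
  # kappa = 50: almost deterministic phase
  tr50 <- generate_locked_spike_train(phase, fs, rate = 5, kappa = 50,
                                      mu = pi, duration_s = 120, seed = 4)
  expect_gt(phase_locking(tr50, phase, fs)$resultant, 0.97)
})

test_that("identical config and seed give a bit-identical session", {
  cfg <- synth_config(duration_s = 30, seed = 11)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$lfp, s2$lfp)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$truth, s2$truth)
})

test_that("generated spectra peak in the RR band, and in theta inside bursts", {
  s <- generate_session(synth_config(duration_s = 300, seed = 21))
  x <- s$lfp[, 1]
  psd <- welch_psd(x, s$fs_lfp)
  # a local spectral maximum inside the RR band (theta dominates globally)
  p <- psd$power
  is_local_max <- c(FALSE, p[-c(1, length(p))] > p[-c(length(p) - 1,
                                                      length(p))] &
                      p[-c(1, length(p))] > p[-c(1, 2)], FALSE)
  expect_true(any(is_local_max & psd$freq >= 2 & psd$freq <= 4))
  tb <- s$truth$bursts[s$truth$bursts$region == "OB", ]
  tb <- tb[which.max(tb$stop - tb$start), ]
  seg <- x[(floor(tb$start * 1000) + 1):floor(tb$stop * 1000)]
  pb <- welch_psd(seg, s$fs_lfp, window_s = min(4, length(seg) / 2000))
  selb <- pb$freq >= 4 & pb$freq <= 12
  expect_gt(max(pb$power[selb]), max(pb$power[pb$freq > 12 & pb$freq < 30]))
})

test_that("zero-amplitude bursts are invisible to the detector", {
  cfg <- synth_config(duration_s = 600, seed = 31, burst_amp = 0)
  s <- generate_session(cfg)
  ev <- detect_theta_bursts(s$lfp[, 1], s$fs_lfp)
  expect_lte(nrow(ev), 1)
})

test_that("driven units copy source spikes at the configured delay", {
  s <- generate_session(synth_config(duration_s = 300, seed = 41))
  src <- s$spikes$time[s$spikes$unit_id == "ob_u1"]
  drv <- s$spikes$time[s$spikes$unit_id == "lec_mono"]
  # each copied spike lies within 5 ms +/- 0.5 ms of some source spike
  d <- vapply(drv, function(t0) min(abs(t0 - src - 0.005)), numeric(1))
  expect_gt(mean(d < 0.0006), 0.25) # drive_prob 0.4 on top of own firing
})
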