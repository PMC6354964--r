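test_that("band-pass filter has the designed frequency response", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  in_band <- sin(2 * pi * 8 * t)
  out_band <- sin(2 * pi * 50 * t)
  yi <- bandpass_filter(in_band, fs, band("theta"))
  yo <- bandpass_filter(out_band, fs, band("theta"))
  mid <- seq(2 * fs, 8 * fs) # avoid filter edge transients
  expect_gte(max(abs(yi[mid])), 0.95)
  expect_gte(-20 * log10(max(abs(yo[mid]))), 20)
  expect_equal(bandpass_filter(rep(0, fs), fs, band("theta")), rep(0, fs))
  expect_error(bandpass_filter(in_band, fs, nc_band("bad", 100, 600)),
               "Nyquist")
})

test_that("Welch band power satisfies Parseval's identity", {
  fs <- 250
  x <- sin(2 * pi * 8 * seq(0, 40, by = 1 / fs))
  expect_equal(welch_band_power(x, fs, band("theta")), 0.5,
               tolerance = 0.02)
  set.seed(1)
  wn <- rnorm(20000, sd = 2)
  expect_equal(welch_band_power(wn, fs, nc_band("full", 0.25, 124.75)), 4,
               tolerance = 0.05)
  expect_equal(welch_band_power(rep(0, 5000), fs, band("theta")), 0)
  expect_error(welch_band_power(x[1:100], fs, band("theta")), "window")
})

test_that("band power is near-additive over disjoint bands and bounded by broadband", {
  fs <- 500
  set.seed(7)
  for (i in 1:5) {
    x <- neocoupling:::one_over_f_noise(10 * fs, fs, 1, 10) +
      sin(2 * pi * 8 * seq_len(10 * fs) / fs) * runif(1, 0, 20)
    lo <- welch_band_power(x, fs, nc_band("a", 2, 10))
    hi <- welch_band_power(x, fs, nc_band("b", 10.25, 30))
    un <- welch_band_power(x, fs, nc_band("ab", 2, 30))
    expect_equal(lo + hi, un, tolerance = 0.02)
    expect_lte(un, welch_band_power(x, fs, nc_band("broad", 0.25, 249)))
  }
})

test_that("Morlet spectrogram localizes tones and tracks a chirp", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  grid <- seq(1, 20, by = 0.5)
  sp <- morlet_spectrogram(sin(2 * pi * 8 * t), fs, grid)
  expect_equal(sp$freqs[which.max(sp$time_avg)], 8)
  expect_equal(sp$time_avg, rowMeans(sp$power))
  # linear chirp 2 -> 12 Hz: ridge within 1 Hz of instantaneous frequency
  f_inst <- 2 + (12 - 2) * t / max(t)
  chirp <- sin(2 * pi * (2 * t + (12 - 2) * t^2 / (2 * max(t))))
  spc <- morlet_spectrogram(chirp, fs, grid, downsample = 25L)
  keep <- spc$times > 2 & spc$times < 18 # skip edges
  ridge <- spc$freqs[apply(spc$power[, keep], 2, which.max)]
  expect_lt(max(abs(ridge - (2 + 10 * spc$times[keep] / max(t)))), 1)
  sp0 <- morlet_spectrogram(rep(0, 1000), fs, grid)
  expect_true(all(sp0$power == 0))
})

test_that("respiration statistics recover cycle frequency", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  rs <- respiration_stats(sin(2 * pi * 2.4 * t), fs)
  expect_equal(rs$median_freq, 2.4, tolerance = 0.01)
  # frequency-modulated breathing stays inside its modulation range
  f_inst <- 2.5 + 0.5 * sin(2 * pi * t / 15)
  fm <- sin(2 * pi * cumsum(f_inst) / fs)
  rs2 <- respiration_stats(fm, fs)
  expect_true(rs2$median_freq >= 2 && rs2$median_freq <= 3)
  expect_error(respiration_stats(rep(0, 10 * fs), fs), "no respiration")
})
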