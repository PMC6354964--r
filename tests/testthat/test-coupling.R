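test_that("instantaneous phase follows the peak/trough convention", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 8 * t)
  ph <- instantaneous_phase(x, fs, band("theta"))
  mid <- seq(2 * fs, 8 * fs)
  peaks <- mid[x[mid] > 0.999]
  troughs <- mid[x[mid] < -0.999]
  expect_lt(max(abs(ph[peaks])), 0.1)
  expect_gt(min(abs(ph[troughs])), pi - 0.1)
  dphi <- diff(neocoupling:::wrap_pi(ph[mid]))
  dphi <- dphi[abs(dphi) < pi]
  expect_equal(mean(dphi) * fs, 2 * pi * 8, tolerance = 0.01)
})

test_that("PPC equals its O(N^2) definition and closed-form limits", {
  fs <- 1000
  # degenerate: all phases equal -> PPC = R = 1
  ph_const <- rep(1.2, 10 * fs)
  pl <- phase_locking(seq(0.5, 8, by = 0.5), ph_const, fs)
  expect_equal(pl$ppc, 1)
  expect_equal(pl$resultant, 1)
  # antipodal pair: exact PPC = -1, R = 0
  ph2 <- c(rep(0, fs), rep(pi, fs))
  pl2 <- phase_locking(c(0.5, 1.5), ph2, fs)
  expect_equal(pl2$ppc, -1)
  expect_equal(pl2$resultant, 0, tolerance = 1e-12)
  expect_error(phase_locking(0.5, ph2, fs), "insufficient spikes")
  # closed form == brute force on irregular samples
  set.seed(21)
  for (i in 1:5) {
    th <- runif(200, -pi, pi)
    ph_series <- rep(th, each = 5)
    times <- (seq(1, length(ph_series), by = 5) - 1) / fs
    pl3 <- phase_locking(times, ph_series, fs)
    expect_equal(pl3$ppc, ppc_bruteforce(th), tolerance = 1e-12)
  }
  # von Mises sample: closed form, preferred phase, Rayleigh significance
  set.seed(22)
  th_vm <- rvonmises(1000, pi, 2)
  ph_vm <- rep(th_vm, each = 2)
  times_vm <- (seq(1, length(ph_vm), by = 2) - 1) / fs
  pl4 <- phase_locking(times_vm, ph_vm, fs)
  expect_equal(pl4$ppc, ppc_vonmises(2), tolerance = 0.05)
  expect_lt(abs(neocoupling:::wrap_pi(pl4$pref_phase - pi)), 0.15)
  expect_lt(pl4$p_rayleigh, 1e-6)
  expect_true(pl4$significant)
})

test_that("PPC is unbiased in spike count while R^2 is not", {
  set.seed(23)
  stat_at_n <- function(n, reps = 1500) {
    t(replicate(reps, {
      th <- rvonmises(n, 0, 1)
      R2 <- Mod(mean(exp(1i * th)))^2
      c(ppc = (n * R2 - 1) / (n - 1), r2 = R2)
    }))
  }
  s50 <- stat_at_n(50)
  s500 <- stat_at_n(500)
  nr <- nrow(s50)
  se <- sqrt(sd(s50[, "ppc"])^2 / nr + sd(s500[, "ppc"])^2 / nr)
  expect_lt(abs(mean(s50[, "ppc"]) - mean(s500[, "ppc"])), 3 * se)
  se_r2 <- sqrt(sd(s50[, "r2"])^2 / nr + sd(s500[, "r2"])^2 / nr)
  expect_gt(abs(mean(s50[, "r2"]) - mean(s500[, "r2"])), 3 * se_r2)
})

test_that("imaginary coherence ignores zero-lag mixtures but sees true lags", {
  fs <- 1000
  n <- 60 * fs
  set.seed(24)
  src <- rnorm(n)
  x <- 2 * src
  y <- -0.7 * src
  co <- imaginary_coherence(x, y, fs, seed = 1)
  expect_gte(mean(abs(co$icoh) <= co$threshold), 0.95)
  expect_lt(max(abs(co$icoh)), 1e-10) # exact zero for a pure mixture
  # 8 Hz quarter-cycle delay -> supra-threshold peak at 8 Hz
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  xq <- sin(2 * pi * 8 * t) + rnorm(n)
  k <- round(fs / 8 / 4)
  yq <- c(rep(0, k), sin(2 * pi * 8 * t))[1:n] + rnorm(n)
  cq <- imaginary_coherence(xq, yq, fs, seed = 2)
  j <- which.min(abs(cq$freq - 8))
  expect_equal(cq$freq[which.max(abs(cq$icoh))], 8)
  expect_gt(abs(cq$icoh[j]), cq$threshold[j])
})

test_that("phase-lag histograms respect the leading-signal convention", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(25)
  x <- sin(2 * pi * 8 * t) + 0.2 * rnorm(length(t))
  h0 <- phase_lag_histogram(x, x, fs, band("theta"))
  expect_lt(abs(h0$circ_mean), 0.05)
  expect_gt(h0$resultant, 0.99)
  k <- round(fs / 8 / 4) # quarter cycle: x leads y
  y <- c(rep(0, k), x)[seq_along(x)]
  hq <- phase_lag_histogram(x, y, fs, band("theta"))
  expect_equal(hq$circ_mean, pi / 2, tolerance = 0.1)
  hi <- phase_lag_histogram(rnorm(20000), rnorm(20000), fs, band("theta"))
  expect_lt(hi$resultant, 0.1)
})

test_that("band-limited cross-correlation obeys the shift theorem", {
  fs <- 1000
  set.seed(26)
  x <- neocoupling:::one_over_f_noise(30 * fs, fs, 1, 1) +
    sin(2 * pi * 8 * seq_len(30 * fs) / fs)
  r0 <- lfp_max_crosscorr(x, x, fs, band("theta"))
  expect_equal(r0$max_corr, 1, tolerance = 1e-6)
  expect_equal(r0$lag_ms, 0)
  y <- c(rep(0, 25), x)[seq_along(x)]
  expect_equal(lfp_max_crosscorr(x, y, fs, band("theta"))$lag_ms, 25)
  # null peak over a handful of lags stays inside the 3-sigma band
  n <- 20000
  rn <- lfp_max_crosscorr(rnorm(n), rnorm(n), fs, nc_band("wide", 1, 400),
                          max_lag_ms = 5)
  expect_lt(rn$max_corr, 3 / sqrt(n))
})

test_that("cross-covariance recovers imposed delays with the lag convention", {
  set.seed(27)
  a <- sort(runif(3000, 0, 600))
  for (d in c(2, 5, 10, 36)) {
    cc <- spike_crosscovariance(a, sort(a + d / 1000), 600, seed = d)
    expect_lte(abs(glance(cc)$peak_lag_ms - (-d)), 1)
  }
  # identical trains: dominant peak at zero lag
  cc0 <- spike_crosscovariance(a, a, 600, seed = 99)
  expect_equal(glance(cc0)$peak_lag_ms, 0)
  expect_equal(classify_connectivity(cc0), "undirected_zero_lag")
  expect_error(
    spike_crosscovariance(sort(runif(10, 0, 600)), a, 600, seed = 1),
    "'a' fails the rate filter")
})

test_that("connectivity classes follow the mono/poly lag windows", {
  fake <- function(peak, z = 5) {
    lags <- -50:50
    zv <- numeric(101)
    zv[lags == peak] <- z
    structure(list(lags_ms = lags, z = zv, threshold = 2,
                   sig_lags_ms = if (is.null(peak)) numeric(0) else peak,
                   n_a = 100, n_b = 100, binsize_ms = 1),
              class = "nc_crosscov")
  }
  expect_equal(classify_connectivity(fake(-5)), "mono_ab")
  expect_equal(classify_connectivity(fake(-36)), "poly_ab")
  expect_equal(classify_connectivity(fake(7)), "mono_ba")
  expect_equal(classify_connectivity(fake(22)), "poly_ba")
  expect_equal(classify_connectivity(fake(0)), "undirected_zero_lag")
  none <- fake(-5)
  none$sig_lags_ms <- numeric(0)
  expect_equal(classify_connectivity(none), "none")
})
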