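test_that("session write/read round-trips field by field", {
  s <- make_tiny_session(dur = 20, seed = 2)
  path <- withr::local_tempdir()
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(s2$session_id, s$session_id)
  expect_equal(s2$fs_lfp, s$fs_lfp)
  expect_equal(unname(s2$lfp), unname(s$lfp), tolerance = 1e-12)
  expect_equal(s2$channels, s$channels)
  expect_equal(s2$spikes, s$spikes, tolerance = 1e-12)
  expect_equal(s2$respiration$x, s$respiration$x, tolerance = 1e-12)
  expect_equal(s2$truth$bursts, s$truth$bursts, tolerance = 1e-12)
  expect_equal(s2$truth$rr_freq, s$truth$rr_freq)
})

test_that("loading a nonexistent bundle reports file not found", {
  expect_error(read_session(file.path(tempdir(), "no-such-session")),
               "file not found")
})

test_that("validation names the offending field", {
  s <- make_tiny_session(dur = 10, seed = 3)
  bad <- s
  bad$spikes <- tibble::tibble(unit_id = "u1", region = "OB",
                               time = c(3, 1))
  expect_error(validate_session(bad), "unsorted spike_train")
  bad2 <- s
  bad2$spikes <- tibble::tibble(unit_id = "u1", region = "OB", time = 99)
  expect_error(validate_session(bad2), "outside")
  expect_error(recording_session("x", fs_lfp = 100,
                                 lfp = matrix(0, 1000, 1),
                                 channels = tibble::tibble(
                                   channel = "c1", region = "OB",
                                   layer = "MCL")),
               "fs_lfp")
  expect_error(recording_session("x", fs_lfp = 1000,
                                 lfp = matrix(0, 1000, 2),
                                 channels = tibble::tibble(
                                   channel = "c1", region = "OB",
                                   layer = "MCL")),
               "channels")
})

test_that("result CSVs are deterministic and cover every family", {
  s <- make_tiny_session(dur = 60, seed = 4)
  res <- run_full_analysis(s, analysis_params(seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_results(res, dir)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths), paste0(
    c("burst_events", "burst_summary", "cooccurrence", "unit_rates",
      "phase_locking", "coherence", "coherence_bands", "phase_lags",
      "crosscov", "connectivity", "perturbation", "log"), ".csv"))
  h1 <- tools::md5sum(paths)
  write_results(res, dir)
  expect_identical(unname(tools::md5sum(paths)), unname(h1))
  # two units x two regions x two rhythms
  pl <- readr::read_csv(file.path(dir, "phase_locking.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(pl), 2 * 4)
})

test_that("a session without spikes still yields field-level tables", {
  s <- make_tiny_session(dur = 60, seed = 5)
  s$spikes <- s$spikes[0, ]
  res <- run_full_analysis(s, analysis_params(seed = 1))
  expect_gt(nrow(res$burst_events), 0)
  expect_gt(nrow(res$coherence), 0)
  expect_equal(nrow(res$phase_locking), 0)
  expect_equal(nrow(res$connectivity), 0)
  dir <- withr::local_tempdir()
  paths <- write_results(res, dir)
  pl <- readr::read_csv(file.path(dir, "phase_locking.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(pl), 0)
})

test_that("run_full_analysis is a pure function of session and params", {
  s <- make_tiny_session(dur = 60, seed = 6)
  p <- analysis_params(seed = 33)
  r1 <- run_full_analysis(s, p)
  r2 <- run_full_analysis(s, p)
  expect_identical(r1$burst_events, r2$burst_events)
  expect_identical(r1$phase_locking, r2$phase_locking)
  expect_identical(r1$coherence, r2$coherence)
  expect_identical(r1$crosscov, r2$crosscov)
  expect_identical(r1$connectivity, r2$connectivity)
})
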