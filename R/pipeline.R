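#' Analysis parameters
#'
#' All tunable settings of the pipeline in one list. Defaults follow the
#' conventions of the neonatal coupling analyses this package implements:
#' a strict 0.05 Hz unit-inclusion rate, 60% burst temporal-overlap rule,
#' monosynaptic 1-10 ms and polysynaptic 10-50 ms lag windows, a
#' 4-30 Hz envelope band with mean + 2 SD burst-core threshold, and
#' 200-surrogate Monte Carlo significance bands.
#'
#' @param rate_min Unit inclusion rate, Hz (strict `>`).
#' @param overlap_frac Burst co-occurrence overlap fraction.
#' @param mono_lag,poly_lag Connectivity lag windows, ms; the mono window
#'   must lie below the poly window.
#' @param burst_env_band Envelope band for burst detection.
#' @param burst_smooth_s Envelope smoothing window, s.
#' @param burst_thresh_sd Core threshold in envelope SDs above the mean.
#' @param burst_core_min_s Minimum time the envelope must hold the core
#'   threshold before an event is considered, s.
#' @param burst_min_dur_s Minimum event duration, s.
#' @param burst_merge_gap_s Events closer than this are merged, s.
#' @param burst_guard_s Guard band around events for non-burst power, s.
#' @param coh_window_s,coh_overlap Welch settings for coherence.
#' @param n_surrogates Surrogates for coherence and cross-covariance
#'   significance (>= 100).
#' @param alpha Significance level.
#' @param crosscov_binsize_ms,crosscov_max_lag_ms,crosscov_smooth_sd_ms,crosscov_jitter_ms
#'   Cross-covariance settings, ms.
#' @param seed Integer seed consumed by every stochastic stage.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(rate_min = 0.05, overlap_frac = 0.60,
                            mono_lag = c(1, 10), poly_lag = c(10, 50),
                            burst_env_band = nc_band("burst_env", 4, 30),
                            burst_smooth_s = 0.2, burst_thresh_sd = 2,
                            burst_core_min_s = 0.4,
                            burst_min_dur_s = 1, burst_merge_gap_s = 0.3,
                            burst_guard_s = 0.5, coh_window_s = 4,
                            coh_overlap = 0.5, n_surrogates = 200,
                            alpha = 0.05, crosscov_binsize_ms = 1,
                            crosscov_max_lag_ms = 50,
                            crosscov_smooth_sd_ms = 2,
                            crosscov_jitter_ms = 25, seed = 1L) {
  stopifnot(overlap_frac > 0, overlap_frac <= 1,
            mono_lag[2] <= poly_lag[1], n_surrogates >= 100)
  structure(as.list(environment()), class = "analysis_params")
}

#' Run the full coupling analysis
#'
#' Drives every analysis stage on one session: burst detection and summary
#' per region, cross-region burst co-occurrence, per-unit firing rates by
#' network state, spike-field phase locking to the RR and theta rhythms of
#' both the unit's own and the other region (theta restricted to detected
#' bursts), imaginary coherence with a surrogate threshold, band-limited
#' phase-lag histograms, spike-spike cross-covariance with connectivity
#' classification for all rate-filtered cross-region pairs, and stimulus
#' effects when non-baseline epochs are present. Pair stages require both an
#' OB and an LEC channel and are skipped (with a logged notice) otherwise.
#' The result is a pure function of `(session, params)`: repeated calls
#' agree exactly.
#'
#' @param session A `recording_session`.
#' @param params An [analysis_params()].
#' @return A list of class `nc_results` holding tibbles `burst_events`,
#'   `burst_summary`, `cooccurrence`, `unit_rates`, `phase_locking`,
#'   `coherence`, `coherence_bands`, `phase_lags`, `crosscov`,
#'   `connectivity`, `perturbation` and the stage `log`.
#' @export
run_full_analysis <- function(session, params = analysis_params()) {
  validate_session(session)
  p <- params
  fs <- session$fs_lfp
  if (fs > 1000) {
    dec <- apply(session$lfp, 2L, function(col) {
      decimate_lfp(col, fs, 1000)$x
    })
    session$lfp <- dec
    fs <- 1000
    session$fs_lfp <- 1000
  }
  dur <- session_duration(session)
  log <- tibble::tibble(stage = character(0), status = character(0),
                        message = character(0))
  note <- function(stage, status, msg = "") {
    log <<- dplyr::bind_rows(log, tibble::tibble(stage = stage,
                                                 status = status,
                                                 message = msg))
  }
  regions <- intersect(c("OB", "LEC", "PIR"), unique(session$channels$region))

  # --- bursts per region
  burst_events <- list()
  burst_sum <- list()
  for (reg in regions) {
    x <- region_channel(session, reg)
    ev <- detect_theta_bursts(x, fs, p)
    burst_events[[reg]] <- dplyr::mutate(ev, region = reg, .before = 1L)
    burst_sum[[reg]] <- dplyr::mutate(
      burst_summary(ev, x, fs, guard_s = p$burst_guard_s),
      region = reg, .before = 1L)
  }
  burst_events <- dplyr::bind_rows(burst_events)
  burst_sum <- dplyr::bind_rows(burst_sum)
  note("bursts", "ok")
  region_bursts <- function(reg) {
    ev <- burst_events[burst_events$region == reg, ]
    ev[, c("start", "stop")]
  }

  pair_ok <- all(c("OB", "LEC") %in% regions)
  if (!pair_ok) {
    note("pair_stages", "skipped", "need both an OB and an LEC channel")
  }

  # --- co-occurrence
  cooccurrence <- tibble::tibble()
  if (pair_ok) {
    co <- burst_cooccurrence(region_bursts("OB"), region_bursts("LEC"),
                             p$overlap_frac)
    cooccurrence <- tibble::tibble(
      reference = c("OB", "LEC", "union"),
      frac_cooccurring = c(co$frac_a, co$frac_b, co$frac_union))
    note("cooccurrence", "ok")
  }

  # --- unit state rates
  units <- dplyr::distinct(session$spikes, .data$unit_id, .data$region) |>
    dplyr::arrange(.data$region, .data$unit_id)
  unit_rates <- tibble::tibble()
  if (nrow(units) > 0L) {
    unit_rates <- dplyr::bind_rows(lapply(seq_len(nrow(units)), function(i) {
      u <- units[i, ]
      reg <- if (u$region %in% regions) u$region else regions[1L]
      dplyr::mutate(rates_by_state(unit_times(session, u$unit_id),
                                   region_bursts(reg), dur),
                    unit_id = u$unit_id, region = u$region, .before = 1L)
    }))
    note("unit_rates", "ok")
  }

  # --- spike-field phase locking: own- and cross-region RR and theta
  phase_cache <- list()
  get_phase <- function(reg, bname) {
    key <- paste(reg, bname)
    if (is.null(phase_cache[[key]])) {
      phase_cache[[key]] <<- instantaneous_phase(
        region_channel(session, reg), fs, band(bname))
    }
    phase_cache[[key]]
  }
  phase_locking_tbl <- tibble::tibble()
  if (nrow(units) > 0L) {
    rows <- list()
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      tt <- unit_times(session, u$unit_id)
      for (reg in regions) {
        for (bname in c("rr", "theta")) {
          restrict <- if (bname == "theta") region_bursts(reg) else NULL
          res <- tryCatch(
            phase_locking(tt, get_phase(reg, bname), fs, restrict,
                          alpha = p$alpha),
            error = function(e) NULL)
          if (!is.null(res)) {
            rows[[length(rows) + 1L]] <- dplyr::mutate(
              res, unit_id = u$unit_id, unit_region = u$region,
              rhythm = paste0(reg, "_", bname), .before = 1L)
          }
        }
      }
    }
    phase_locking_tbl <- dplyr::bind_rows(rows)
    note("phase_locking", "ok")
  }

  # --- field-field coupling
  coherence_tbl <- tibble::tibble()
  coherence_bands <- tibble::tibble()
  phase_lags <- tibble::tibble()
  if (pair_ok) {
    xo <- region_channel(session, "OB")
    xl <- region_channel(session, "LEC")
    coh <- tryCatch(
      imaginary_coherence(xo, xl, fs, p$coh_window_s, p$coh_overlap,
                          p$n_surrogates, p$alpha, seed = p$seed + 101L),
      error = function(e) {
        note("coherence", "error", conditionMessage(e))
        NULL
      })
    if (!is.null(coh)) {
      coherence_tbl <- tibble::tibble(freq = coh$freq, icoh = coh$icoh,
                                      threshold = coh$threshold)
      coherence_bands <- coh$band_means
      note("coherence", "ok")
    }
    for (bname in c("rr", "theta")) {
      restrict <- if (bname == "theta") region_bursts("OB") else NULL
      pl <- phase_lag_histogram(xo, xl, fs, band(bname), restrict)
      phase_lags <- dplyr::bind_rows(phase_lags, tibble::tibble(
        band = bname, bin_lo = pl$breaks[-length(pl$breaks)],
        bin_hi = pl$breaks[-1L], count = pl$counts,
        circ_mean = pl$circ_mean, resultant = pl$resultant))
    }
    note("phase_lags", "ok")
  }

  # --- spike-spike cross-covariance for rate-filtered OB x LEC pairs
  crosscov_tbl <- tibble::tibble()
  connectivity <- tibble::tibble()
  if (pair_ok && nrow(units) > 0L) {
    kept <- filter_trains_by_rate(session$spikes, dur, p$rate_min)
    ob_units <- unique(kept$unit_id[kept$region == "OB"])
    lec_units <- unique(kept$unit_id[kept$region == "LEC"])
    k <- 0L
    for (ua in sort(ob_units)) {
      for (ub in sort(lec_units)) {
        k <- k + 1L
        cc <- spike_crosscovariance(
          unit_times(session, ua), unit_times(session, ub), dur,
          p$crosscov_binsize_ms, p$crosscov_max_lag_ms,
          p$crosscov_smooth_sd_ms, p$n_surrogates, p$crosscov_jitter_ms,
          p$alpha, p$rate_min, seed = p$seed + 1000L + k)
        lab <- classify_connectivity(cc, p$mono_lag, p$poly_lag)
        crosscov_tbl <- dplyr::bind_rows(crosscov_tbl, tibble::tibble(
          unit_a = ua, unit_b = ub, lag_ms = cc$lags_ms, z = cc$z,
          threshold = cc$threshold))
        pk <- if (length(cc$sig_lags_ms)) {
          si <- which(cc$lags_ms %in% cc$sig_lags_ms)
          cc$lags_ms[si[which.max(abs(cc$z[si]))]]
        } else {
          NA_real_
        }
        connectivity <- dplyr::bind_rows(connectivity, tibble::tibble(
          unit_a = ua, unit_b = ub, peak_lag_ms = pk,
          n_sig_lags = length(cc$sig_lags_ms), classification = lab))
      }
    }
    note("crosscov", "ok", sprintf("%d pairs", k))
  }

  # --- perturbation
  perturbation <- tibble::tibble()
  if (nrow(session$epochs) > 0L &&
      length(setdiff(unique(session$epochs$label), "baseline")) > 0L) {
    perturbation <- tryCatch(stimulus_effects(session), error = function(e) {
      note("perturbation", "error", conditionMessage(e))
      tibble::tibble()
    })
    if (nrow(perturbation)) note("perturbation", "ok")
  }

  structure(list(burst_events = burst_events, burst_summary = burst_sum,
                 cooccurrence = cooccurrence, unit_rates = unit_rates,
                 phase_locking = phase_locking_tbl,
                 coherence = coherence_tbl,
                 coherence_bands = coherence_bands, phase_lags = phase_lags,
                 crosscov = crosscov_tbl, connectivity = connectivity,
                 perturbation = perturbation, log = log),
            class = "nc_results")
}

#' @export
print.nc_results <- function(x, ...) {
  cat("<nc_results>\n")
  for (nm in setdiff(names(x), "log")) {
    cat(sprintf("  %-16s %d rows\n", nm, nrow(x[[nm]])))
  }
  bad <- x$log[x$log$status != "ok", ]
  if (nrow(bad)) {
    cat("  notices:\n")
    for (i in seq_len(nrow(bad))) {
      cat("   -", bad$stage[i], bad$status[i], bad$message[i], "\n")
    }
  }
  invisible(x)
}

#' Write a result bundle as CSV tables
#'
#' One CSV per result family, with deterministic row order, so repeated
#' writes of the same bundle are byte-identical. Empty tables produce
#' headers-only files.
#'
#' @param results An `nc_results` bundle.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "nc_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  order_cols <- list(
    burst_events = c("region", "start"),
    burst_summary = "region",
    unit_rates = c("region", "unit_id"),
    phase_locking = c("unit_region", "unit_id", "rhythm"),
    crosscov = c("unit_a", "unit_b", "lag_ms"),
    connectivity = c("unit_a", "unit_b"),
    perturbation = c("region", "label", "band", "trial"))
  paths <- character(0)
  for (nm in names(results)) {
    tbl <- results[[nm]]
    if (!is.data.frame(tbl)) next
    oc <- intersect(order_cols[[nm]] %||% character(0), names(tbl))
    if (length(oc)) tbl <- dplyr::arrange(tbl, dplyr::across(
      dplyr::all_of(oc)))
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tbl, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
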