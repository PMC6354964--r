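#' Optogenetic modulation index
#'
#' Bounded symmetric contrast of stimulus versus pre-stimulus power,
#' `OMI = (p_stim - p_pre) / (p_stim + p_pre)`, in `[-1, 1]`, antisymmetric
#' under swapping its arguments; near +1 for strong activation, near 0 for
#' no effect.
#'
#' @param p_pre,p_stim Non-negative powers (vectorized), not both zero.
#' @return OMI value(s).
#' @examples
#' omi(1, 3) # 0.5
#' @export
omi <- function(p_pre, p_stim) {
  stopifnot(all(p_pre >= 0), all(p_stim >= 0))
  if (any(p_pre + p_stim == 0)) {
    stop("OMI undefined when both powers are zero", call. = FALSE)
  }
  (p_stim - p_pre) / (p_stim + p_pre)
}

#' Evoked relative change with outlier handling
#'
#' Per-trial ratio of the response measure to its baseline, summarized by
#' the median and interquartile range after removing single-pass
#' interquartile-range outliers (see [remove_outliers_iqr()]). Trials with a
#' non-positive baseline are flagged and excluded rather than producing
#' infinities.
#'
#' @param baseline,response Per-trial scalars (equal length).
#' @return List with `per_trial` (tibble: `trial`, `baseline`, `response`,
#'   `rel_change`, `flagged`) and `summary` (tibble: `median`, `iqr_lo`,
#'   `iqr_hi`, `n_used`, `n_outliers`, `n_flagged`).
#' @export
evoked_relative_change <- function(baseline, response) {
  stopifnot(length(baseline) == length(response))
  flagged <- !(baseline > 0)
  if (any(flagged)) {
    message(sum(flagged), " trial(s) with non-positive baseline flagged ",
            "and excluded")
  }
  ratio <- ifelse(flagged, NA_real_, response / baseline)
  per_trial <- tibble::tibble(trial = seq_along(baseline),
                              baseline = baseline, response = response,
                              rel_change = ratio, flagged = flagged)
  ok <- ratio[!flagged]
  out <- remove_outliers_iqr(ok)
  kept <- out$kept
  summary <- tibble::tibble(
    median = if (length(kept)) stats::median(kept) else NA_real_,
    iqr_lo = if (length(kept)) stats::quantile(kept, 0.25, names = FALSE)
             else NA_real_,
    iqr_hi = if (length(kept)) stats::quantile(kept, 0.75, names = FALSE)
             else NA_real_,
    n_used = length(kept), n_outliers = length(out$removed),
    n_flagged = sum(flagged))
  list(per_trial = per_trial, summary = summary)
}

# Per-interval band area power, with a matched baseline window immediately
# preceding each interval.
epoch_band_power <- function(x, fs, intervals, band, window_s = 2) {
  vapply(seq_len(nrow(intervals)), function(i) {
    i0 <- max(1L, floor(intervals$start[i] * fs) + 1L)
    i1 <- min(length(x), floor(intervals$stop[i] * fs))
    welch_band_power(x[i0:i1], fs, band, window_s = window_s)
  }, numeric(1))
}

#' Stimulus effects on band power
#'
#' For every non-baseline epoch label, computes the band area power in each
#' stimulus interval and in a pre-stimulus window of the same length
#' immediately preceding onset, and reports the per-trial relative change
#' and OMI for the requested bands and regions.
#'
#' @param session A `recording_session` with labelled epochs.
#' @param bands Band tibble (RR/theta/beta by default).
#' @param window_s Welch window for the per-interval power, s.
#' @return Tibble: `region`, `label`, `band`, `trial`, `baseline_power`,
#'   `stim_power`, `rel_change`, `omi`.
#' @export
stimulus_effects <- function(session, bands = NULL, window_s = 2) {
  bands <- bands %||% nc_bands()[nc_bands()$name %in%
                                   c("rr", "theta", "beta"), ]
  labels <- setdiff(unique(session$epochs$label), "baseline")
  regions <- unique(session$channels$region)
  out <- list()
  for (lab in labels) {
    iv <- session$epochs[session$epochs$label == lab, ]
    pre <- iv
    pre$stop <- iv$start
    pre$start <- pmax(0, iv$start - (iv$stop - iv$start))
    for (reg in regions) {
      x <- region_channel(session, reg)
      for (bi in seq_len(nrow(bands))) {
        bnd <- bands[bi, ]
        p_stim <- epoch_band_power(x, session$fs_lfp, iv, bnd, window_s)
        p_pre <- epoch_band_power(x, session$fs_lfp, pre, bnd, window_s)
        out[[length(out) + 1L]] <- tibble::tibble(
          region = reg, label = lab, band = bnd$name,
          trial = seq_along(p_stim), baseline_power = p_pre,
          stim_power = p_stim, rel_change = p_stim / p_pre,
          omi = omi(p_pre, p_stim))
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(region = character(0), label = character(0),
                          band = character(0), trial = integer(0),
                          baseline_power = numeric(0),
                          stim_power = numeric(0), rel_change = numeric(0),
                          omi = numeric(0)))
  }
  dplyr::bind_rows(out)
}
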