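#' Firing rates by network state
#'
#' Splits a spike train into burst and non-burst time and reports the rate
#' in each state plus the percentage of spikes falling inside bursts.
#'
#' @param times Sorted spike times, s.
#' @param bursts Event tibble (`start`, `stop`), within `[0, duration]`.
#' @param duration Recording duration, s.
#' @return One-row tibble: `n_spikes`, `burst_rate`, `nonburst_rate` (Hz;
#'   `NA` when the corresponding state has zero time) and
#'   `pct_in_burst` (`NA` for an empty train).
#' @export
rates_by_state <- function(times, bursts, duration) {
  stopifnot(duration > 0)
  t_burst <- interval_time(bursts)
  t_non <- duration - t_burst
  inside <- in_intervals(times, bursts)
  n_in <- sum(inside)
  n <- length(times)
  tibble::tibble(
    n_spikes = n,
    burst_rate = if (t_burst > 0) n_in / t_burst else NA_real_,
    nonburst_rate = if (t_non > 0) (n - n_in) / t_non else NA_real_,
    pct_in_burst = if (n > 0) 100 * n_in / n else NA_real_)
}

#' Peristimulus response classification
#'
#' Counts spikes per trial in a pre-stimulus window, the stimulus window and
#' a post-stimulus window of the same length, and classifies the unit by
#' paired Wilcoxon signed-rank tests: `"decrease"` when firing drops
#' significantly during the stimulus, `"post_increase"` when firing is
#' unchanged during the stimulus but rises significantly afterwards, else
#' `"unchanged"`. Counts are taken over whole windows rather than bins,
#' which is robust at the low firing rates of neonatal units; binned PSTH
#' counts are returned for display only.
#'
#' @param times Spike times, s.
#' @param stim Stimulus epochs, tibble `start`, `stop` (>= 10 trials).
#' @param alpha Per-unit significance level (no correction across units).
#' @param bin_s PSTH display bin width, s.
#' @return List with `class` (label), `p_during`, `p_post`, per-trial count
#'   tibble `counts`, and the display `psth` tibble.
#' @export
psth_classify_response <- function(times, stim, alpha = 0.05, bin_s = 0.1) {
  if (nrow(stim) < 10L) {
    stop("need at least 10 stimulus repetitions, got ", nrow(stim),
         call. = FALSE)
  }
  w <- stim$stop - stim$start
  count_in <- function(lo, hi) {
    vapply(seq_along(lo), function(i) {
      sum(times >= lo[i] & times < hi[i])
    }, numeric(1))
  }
  pre <- count_in(stim$start - w, stim$start)
  during <- count_in(stim$start, stim$stop)
  post <- count_in(stim$stop, stim$stop + w)
  safe_p <- function(a, b) {
    if (all(a == b)) return(1)
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                        exact = FALSE)$p.value)
  }
  p_during <- safe_p(during, pre)
  p_post <- safe_p(post, pre)
  label <- "unchanged"
  if (p_during < alpha && stats::median(during - pre) < 0) {
    label <- "decrease"
  } else if (p_during >= alpha && p_post < alpha &&
             stats::median(post - pre) > 0) {
    label <- "post_increase"
  }
  # display PSTH relative to stimulus onset, one pre-window to one post-window
  rel <- unlist(lapply(seq_len(nrow(stim)), function(i) {
    sel <- times >= stim$start[i] - w[i] & times < stim$stop[i] + w[i]
    times[sel] - stim$start[i]
  }))
  breaks <- seq(-max(w), 2 * max(w), by = bin_s)
  psth <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    rate = graphics::hist(rel, breaks = breaks, plot = FALSE)$counts /
      (nrow(stim) * bin_s))
  list(class = label, p_during = p_during, p_post = p_post,
       counts = tibble::tibble(trial = seq_len(nrow(stim)), pre = pre,
                               during = during, post = post),
       psth = psth)
}

#' Minimum-rate inclusion filter
#'
#' Keeps units whose mean firing rate strictly exceeds `rate_min`
#' (default 0.05 Hz, the conventional inclusion threshold for neonatal
#' units; a unit at exactly the threshold is excluded).
#'
#' @param spikes Tibble `unit_id`, `region`, `time`.
#' @param duration Recording duration, s.
#' @param rate_min Threshold rate, Hz (strict `>`).
#' @return The filtered spike tibble.
#' @export
filter_trains_by_rate <- function(spikes, duration, rate_min = 0.05) {
  stopifnot(duration > 0)
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::filter(dplyr::n() / duration > rate_min) |>
    dplyr::ungroup()
}
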