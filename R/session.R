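#' Recording session container
#'
#' A recording session bundles everything recorded from one animal under one
#' condition: the multichannel LFP (microvolts), a channel table with region
#' and layer labels, sorted spike trains, an optional respiration trace,
#' labelled epochs (baseline / stimulus / drug ...) and, for synthetic
#' sessions, the generator's ground truth.
#'
#' @param session_id Character identifier.
#' @param fs_lfp LFP sampling rate in Hz (>= 200).
#' @param lfp Numeric matrix, samples x channels.
#' @param channels Tibble with one row per LFP column: `channel`, `region`
#'   (one of `"OB"`, `"LEC"`, `"PIR"`), `layer`.
#' @param spikes Tibble of spike times: `unit_id`, `region`, `time` (s).
#'   Times must be sorted, unique and non-negative within each unit.
#' @param respiration Optional list `list(x = <trace>, fs = <Hz>)`.
#' @param epochs Tibble `label`, `start`, `stop` of half-open intervals
#'   `[start, stop)`; intervals of one label must be sorted and
#'   non-overlapping.
#' @param truth Optional ground truth attached by [generate_session()].
#' @return A validated object of class `recording_session`.
#' @seealso [read_session()], [write_session()], [generate_session()]
#' @export
recording_session <- function(session_id, fs_lfp, lfp, channels,
                              spikes = empty_spikes(), respiration = NULL,
                              epochs = empty_epochs(), truth = NULL) {
  s <- structure(
    list(session_id = session_id, fs_lfp = fs_lfp,
         lfp = as.matrix(lfp), channels = tibble::as_tibble(channels),
         spikes = tibble::as_tibble(spikes), respiration = respiration,
         epochs = tibble::as_tibble(epochs), truth = truth),
    class = "recording_session")
  validate_session(s)
}

empty_spikes <- function() {
  tibble::tibble(unit_id = character(0), region = character(0),
                 time = numeric(0))
}

empty_epochs <- function() {
  tibble::tibble(label = character(0), start = numeric(0), stop = numeric(0))
}

#' @rdname recording_session
#' @param session A `recording_session`.
#' @export
session_duration <- function(session) {
  nrow(session$lfp) / session$fs_lfp
}

#' @rdname recording_session
#' @export
validate_session <- function(session) {
  s <- session
  if (!is.numeric(s$fs_lfp) || s$fs_lfp < 200) {
    stop("invalid fs_lfp: LFP sampling rate must be >= 200 Hz", call. = FALSE)
  }
  if (!is.matrix(s$lfp) || nrow(s$lfp) == 0L) {
    stop("invalid lfp: need a non-empty samples x channels matrix",
         call. = FALSE)
  }
  if (nrow(s$channels) != ncol(s$lfp)) {
    stop("invalid channels: table has ", nrow(s$channels),
         " rows but lfp has ", ncol(s$lfp), " channels", call. = FALSE)
  }
  if (!all(s$channels$region %in% c("OB", "LEC", "PIR"))) {
    stop("invalid channels: region must be one of OB, LEC, PIR",
         call. = FALSE)
  }
  dur <- session_duration(s)
  if (nrow(s$spikes) > 0L) {
    if (any(s$spikes$time < 0) || any(s$spikes$time > dur)) {
      stop("invalid spike_train: spike time outside [0, duration]",
           call. = FALSE)
    }
    bad <- s$spikes |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::summarise(ok = !is.unsorted(.data$time, strictly = TRUE)) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad) > 0L) {
      stop("unsorted spike_train: unit '", bad$unit_id[1L],
           "' has non-increasing spike times", call. = FALSE)
    }
  }
  if (nrow(s$epochs) > 0L) {
    if (any(s$epochs$stop <= s$epochs$start)) {
      stop("invalid epochs: stop must exceed start", call. = FALSE)
    }
    bad <- s$epochs |>
      dplyr::group_by(.data$label) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::summarise(ok = dplyr::n() < 2L ||
                         all(.data$start[-1L] >= .data$stop[-dplyr::n()])) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad) > 0L) {
      stop("invalid epochs: overlapping intervals in label '",
           bad$label[1L], "'", call. = FALSE)
    }
  }
  invisible(s)
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session> ", x$session_id, "\n", sep = "")
  cat("  ", nrow(x$lfp), " samples x ", ncol(x$lfp), " channels @ ",
      x$fs_lfp, " Hz (", round(session_duration(x), 1), " s)\n", sep = "")
  cat("  regions:", paste(unique(x$channels$region), collapse = ", "), "\n")
  cat("  units:", length(unique(x$spikes$unit_id)), " spikes:",
      nrow(x$spikes), "\n")
  if (nrow(x$epochs)) {
    cat("  epochs:", paste(unique(x$epochs$label), collapse = ", "), "\n")
  }
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

# Pick the representative (first listed) LFP channel of a region.
region_channel <- function(session, region) {
  idx <- which(session$channels$region == region)
  if (length(idx) == 0L) return(NULL)
  session$lfp[, idx[1L]]
}

# Spike times of one unit.
unit_times <- function(session, unit_id) {
  session$spikes$time[session$spikes$unit_id == unit_id]
}

#' Read and write the session container
#'
#' Sessions are stored as a plain-text directory bundle: `meta.json`
#' (identifier, sampling rates, channel table, `schema_version`),
#' `lfp.csv` (one column per channel), `spikes.csv`, `epochs.csv`,
#' optional `respiration.csv` and, for synthetic sessions,
#' `truth_bursts.csv` / `truth_units.csv`. The format is self-describing,
#' language-neutral and diff-able.
#'
#' @param path Directory path of the bundle.
#' @param session A `recording_session`.
#' @return `read_session()` returns a validated `recording_session`;
#'   `write_session()` returns `path` invisibly.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) {
    stop("file not found: no session bundle at '", path, "'", call. = FALSE)
  }
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("schema violation: missing meta.json in '", path, "'", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (field in c("session_id", "fs_lfp", "channels")) {
    if (is.null(meta[[field]])) {
      stop("schema violation: meta.json lacks field '", field, "'",
           call. = FALSE)
    }
  }
  lfp <- as.matrix(readr::read_csv(file.path(path, "lfp.csv"),
                                   show_col_types = FALSE))
  spikes <- if (file.exists(file.path(path, "spikes.csv"))) {
    readr::read_csv(file.path(path, "spikes.csv"), show_col_types = FALSE,
                    col_types = "ccd")
  } else {
    empty_spikes()
  }
  epochs <- if (file.exists(file.path(path, "epochs.csv"))) {
    readr::read_csv(file.path(path, "epochs.csv"), show_col_types = FALSE,
                    col_types = "cdd")
  } else {
    empty_epochs()
  }
  respiration <- NULL
  if (file.exists(file.path(path, "respiration.csv"))) {
    r <- readr::read_csv(file.path(path, "respiration.csv"),
                         show_col_types = FALSE)
    respiration <- list(x = r$x, fs = meta$fs_respiration)
  }
  truth <- NULL
  if (file.exists(file.path(path, "truth_bursts.csv"))) {
    truth <- list(
      bursts = readr::read_csv(file.path(path, "truth_bursts.csv"),
                               show_col_types = FALSE, col_types = "cdd"),
      units = readr::read_csv(file.path(path, "truth_units.csv"),
                              show_col_types = FALSE),
      rr_freq = meta$rr_freq)
  }
  recording_session(meta$session_id, meta$fs_lfp, lfp,
                    tibble::as_tibble(meta$channels), spikes, respiration,
                    epochs, truth)
}

#' @rdname read_session
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema_version = "1.0",
               session_id = session$session_id,
               fs_lfp = session$fs_lfp,
               channels = session$channels)
  if (!is.null(session$respiration)) {
    meta$fs_respiration <- session$respiration$fs
  }
  if (!is.null(session$truth)) meta$rr_freq <- session$truth$rr_freq
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lfp <- as.data.frame(session$lfp)
  names(lfp) <- session$channels$channel
  readr::write_csv(lfp, file.path(path, "lfp.csv"))
  readr::write_csv(session$spikes, file.path(path, "spikes.csv"))
  readr::write_csv(session$epochs, file.path(path, "epochs.csv"))
  if (!is.null(session$respiration)) {
    readr::write_csv(tibble::tibble(x = session$respiration$x),
                     file.path(path, "respiration.csv"))
  }
  if (!is.null(session$truth)) {
    readr::write_csv(session$truth$bursts, file.path(path, "truth_bursts.csv"))
    readr::write_csv(session$truth$units, file.path(path, "truth_units.csv"))
  }
  invisible(path)
}
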