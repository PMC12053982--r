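# Synchronized multistream recordings: signal streams (EEG, kinematics) and
# the event-marker stream share one recording clock; markers index the cue
# and every step so that epochs can be cut from any stream by time.

MARKER_LABEL_RE <- "^(BLOCK_START|CUE_GO|CUE_NOGO|STEP_[0-9]+)$"

#' Multichannel signal stream
#'
#' A regularly sampled channels-by-time array with a name, channel labels, a
#' sampling rate and the recording-clock time of the first sample.
#'
#' @param name stream name (e.g. `"eeg"`, `"com"`).
#' @param channel_labels unique channel labels, one per row of `samples`.
#' @param fs_hz sampling rate (> 0).
#' @param start_time_s recording-clock time of sample 1.
#' @param samples numeric matrix, channels x time.
#' @return a `signal_stream`.
#' @export
signal_stream <- function(name, channel_labels, fs_hz, start_time_s, samples) {
  samples <- as.matrix(samples)
  if (fs_hz <= 0) stop_invalid("fs_hz must be > 0")
  if (anyDuplicated(channel_labels)) stop_invalid("channel labels must be unique")
  if (nrow(samples) != length(channel_labels)) {
    stop_invalid("samples has %d rows for %d channel labels",
                 nrow(samples), length(channel_labels))
  }
  rownames(samples) <- channel_labels
  structure(list(name = name, channel_labels = channel_labels,
                 fs_hz = fs_hz, start_time_s = start_time_s,
                 samples = samples),
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("<signal_stream> '%s': %d ch x %d samples @ %g Hz, t0 = %.3f s\n",
              x$name, nrow(x$samples), ncol(x$samples), x$fs_hz, x$start_time_s))
  invisible(x)
}

#' Times of a stream's samples on the recording clock
#' @param stream a `signal_stream`.
#' @return numeric vector, one time per sample.
#' @export
stream_times <- function(stream) {
  stream$start_time_s + (seq_len(ncol(stream$samples)) - 1L) / stream$fs_hz
}

#' Event-marker stream
#'
#' Markers come from the closed vocabulary `BLOCK_START`, `CUE_GO`,
#' `CUE_NOGO`, `STEP_k`, each carrying a recording-clock timestamp and the
#' trial it belongs to.
#'
#' @param label character vector of marker labels.
#' @param timestamp_s non-decreasing numeric timestamps.
#' @param trial_index integer trial index (NA for block-level markers).
#' @param block optional block number.
#' @return a `marker_stream` data.frame.
#' @export
marker_stream <- function(label, timestamp_s, trial_index = NA_integer_,
                          block = NA_integer_) {
  bad <- !grepl(MARKER_LABEL_RE, label)
  if (any(bad)) {
    stop_invalid("marker label(s) outside the vocabulary: %s",
                 paste(unique(label[bad]), collapse = ", "))
  }
  if (is.unsorted(timestamp_s)) stop_invalid("marker timestamps must be non-decreasing")
  out <- data.frame(label = label, timestamp_s = timestamp_s,
                    trial_index = trial_index, block = block)
  class(out) <- c("marker_stream", "data.frame")
  out
}

#' Map streams and markers onto one common clock
#'
#' Each stream (and the marker stream) may carry a constant clock offset;
#' alignment subtracts the offsets so all timestamps live on the common
#' clock. The model is a constant offset per stream — no drift term.
#'
#' @param streams named list of `signal_stream`s.
#' @param markers a `marker_stream`.
#' @param clock_offsets_s named numeric vector of per-stream offsets
#'   (seconds, default 0 for streams not named); element `"markers"` applies
#'   to the marker stream.
#' @return list `streams`, `markers` (a synchronized recording). Markers
#'   falling outside the span of every stream raise an orphan-marker warning.
#' @export
align_streams <- function(streams, markers, clock_offsets_s = numeric(0)) {
  off <- function(nm) if (nm %in% names(clock_offsets_s)) clock_offsets_s[[nm]] else 0
  streams <- lapply(stats::setNames(names(streams), names(streams)), function(nm) {
    s <- streams[[nm]]
    s$start_time_s <- s$start_time_s - off(nm)
    s
  })
  markers$timestamp_s <- markers$timestamp_s - off("markers")
  spans <- lapply(streams, function(s) range(stream_times(s)))
  orphan <- vapply(markers$timestamp_s, function(t) {
    !any(vapply(spans, function(sp) t >= sp[1] && t <= sp[2], logical(1)))
  }, logical(1))
  if (any(orphan)) {
    warning(sprintf("%d orphan marker(s) outside every stream's span", sum(orphan)),
            call. = FALSE)
  }
  list(streams = streams, markers = markers)
}

#' Expected sample count of an epoch
#'
#' Nearest-sample rounding of duration times sampling rate: a 6 s execution
#' at 500 Hz spans 3000 samples, a 1 s execution 500.
#'
#' @param duration_s positive duration (seconds).
#' @param fs_hz sampling rate.
#' @return integer sample count.
#' @export
epoch_sample_count <- function(duration_s, fs_hz) {
  if (any(duration_s <= 0)) stop_invalid("duration must be positive")
  as.integer(round(duration_s * fs_hz))
}

#' Check marker completeness against a schedule
#'
#' Report-only validation: per Go trial, whether the cue and all step markers
#' are present; counts of duplicate cue markers and non-monotone timestamps.
#'
#' @param markers a `marker_stream` (one block's markers).
#' @param block_schedule the `block_schedule` the markers should realize.
#' @return list with `trials` (data.frame: trial_index, is_go, n_cue,
#'   n_steps, complete), `n_incomplete`, `n_duplicate_cues`, `monotone`.
#' @export
validate_markers <- function(markers, block_schedule) {
  trials <- block_schedule$trials
  res <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    m <- markers[!is.na(markers$trial_index) & markers$trial_index == tr$trial_index, ]
    n_cue <- sum(m$label %in% c("CUE_GO", "CUE_NOGO"))
    n_steps <- sum(grepl("^STEP_", m$label))
    need <- if (tr$is_go) nchar(tr$sequence) else 0L
    data.frame(trial_index = tr$trial_index, is_go = tr$is_go,
               n_cue = n_cue, n_steps = n_steps,
               complete = n_cue == 1L && n_steps >= need)
  })
  res <- do.call(rbind, res)
  list(trials = res,
       n_incomplete = sum(!res$complete),
       n_duplicate_cues = sum(res$n_cue > 1L),
       monotone = !is.unsorted(markers$timestamp_s))
}
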