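# Variable-length, marker-defined epochs.
#
# One epoch is one Go-trial sequence execution: it is anchored at the Go cue,
# includes a 200 ms pre-cue baseline window, all six step markers, and 100 ms
# of padding at both ends to absorb wavelet edge effects. Epoch lengths vary
# with execution speed (roughly 0.5-6 s of execution, i.e. 250-3000 samples
# at 500 Hz); the per-step time normalization downstream makes them
# comparable.

#' Epoch object
#'
#' @param trial_index trial the epoch belongs to.
#' @param data channels x time matrix cut from the source stream.
#' @param fs_hz sampling rate.
#' @param t0_s recording-clock time of the first sample.
#' @param cue_offset_s cue time minus `t0_s` (seconds into the epoch).
#' @param step_offsets_s step-marker times relative to the cue, strictly
#'   increasing.
#' @param pad_s padding on each side (seconds).
#' @param baseline_window_s baseline window relative to the cue (must end at
#'   or before the cue).
#' @param channel_labels labels for the rows of `data`.
#' @param block optional block number.
#' @param context_pre,context_post optional channels x time matrices of raw
#'   recording immediately before/after the epoch span. They are not part of
#'   the epoch proper; the wavelet stage uses them as convolution context so
#'   edge handling works on real data instead of a reflected surrogate.
#' @return an `epoch`.
#' @export
epoch <- function(trial_index, data, fs_hz, t0_s, cue_offset_s, step_offsets_s,
                  pad_s = 0.1, baseline_window_s = c(-0.2, 0),
                  channel_labels = rownames(data), block = NA_integer_,
                  context_pre = NULL, context_post = NULL) {
  if (length(step_offsets_s) > 1 && any(diff(step_offsets_s) <= 0)) {
    stop_invalid("step offsets must be strictly increasing")
  }
  if (pad_s < 0) stop_invalid("pad_s must be >= 0")
  if (baseline_window_s[2] > 0) stop_invalid("baseline window must precede the cue")
  structure(list(trial_index = trial_index, data = as.matrix(data),
                 fs_hz = fs_hz, t0_s = t0_s, cue_offset_s = cue_offset_s,
                 step_offsets_s = step_offsets_s, pad_s = pad_s,
                 baseline_window_s = baseline_window_s,
                 channel_labels = channel_labels, block = block,
                 context_pre = context_pre, context_post = context_post),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> trial %d: %d ch x %d samples @ %g Hz, %d steps over %.2f s\n",
              x$trial_index, nrow(x$data), ncol(x$data), x$fs_hz,
              length(x$step_offsets_s), max(x$step_offsets_s)))
  invisible(x)
}

# Nearest-sample index of a recording-clock time within a stream (1-based).
time_to_sample <- function(t_s, stream) {
  as.integer(round((t_s - stream$start_time_s) * stream$fs_hz)) + 1L
}

#' Cut one epoch per valid Go trial
#'
#' For every trial with a `CUE_GO` marker and a full set of `STEP_k` markers,
#' cuts `[cue + baseline_start - pad, last step + pad]` from the stream by
#' nearest-sample rounding. NoGo trials and trials with missing step markers
#' are skipped (the skip reason is collected in the `skipped` attribute).
#'
#' @param stream the `signal_stream` to epoch (EEG at 500 Hz or kinematics at
#'   100 Hz — identical marker logic).
#' @param markers a `marker_stream` on the same clock.
#' @param n_steps expected steps per sequence (default 6).
#' @param pad_s padding seconds each side (default 0.1).
#' @param baseline_window_s baseline window relative to the cue.
#' @param anchor `"cue"` (default) anchors segments at the Go cue so the six
#'   per-step segments are cue->s1, s1->s2, ..., s5->s6; `"first_step"`
#'   starts the execution span at step 1 (five segments).
#' @param context_s seconds of surrounding raw recording attached to each
#'   epoch (clipped to the recording) as wavelet convolution context; 0
#'   disables.
#' @return list of [epoch()] objects; attribute `skipped` is a data.frame of
#'   skipped trials with reasons.
#' @export
extract_sequence_epochs <- function(stream, markers, n_steps = 6, pad_s = 0.1,
                                    baseline_window_s = c(-0.2, 0),
                                    anchor = c("cue", "first_step"),
                                    context_s = 0.5) {
  anchor <- match.arg(anchor)
  idx <- which(markers$label == "CUE_GO")
  epochs <- list()
  skipped <- list()
  nt <- ncol(stream$samples)
  for (i in idx) {
    tr <- markers$trial_index[i]
    cue_t <- markers$timestamp_s[i]
    same_block <- if (is.na(markers$block[i])) rep(TRUE, nrow(markers)) else
      !is.na(markers$block) & markers$block == markers$block[i]
    steps <- markers[same_block & !is.na(markers$trial_index) &
                       markers$trial_index == tr & grepl("^STEP_", markers$label), ]
    steps <- steps[steps$timestamp_s > cue_t, ]
    if (nrow(steps) < n_steps) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(trial_index = tr, reason = sprintf("missing step markers (%d/%d)",
                                                      nrow(steps), n_steps))
      next
    }
    steps <- steps[order(steps$timestamp_s), ][seq_len(n_steps), ]
    t_start <- cue_t + baseline_window_s[1] - pad_s
    t_end <- max(steps$timestamp_s) + pad_s
    i0 <- time_to_sample(t_start, stream)
    i1 <- time_to_sample(t_end, stream)
    if (i0 < 1L || i1 > nt) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(trial_index = tr, reason = "epoch extends beyond recording")
      next
    }
    t0 <- stream$start_time_s + (i0 - 1L) / stream$fs_hz
    nctx <- round(context_s * stream$fs_hz)
    c0 <- max(1L, i0 - nctx)
    c1 <- min(nt, i1 + nctx)
    epochs[[length(epochs) + 1L]] <- epoch(
      trial_index = tr,
      data = stream$samples[, i0:i1, drop = FALSE],
      fs_hz = stream$fs_hz, t0_s = t0,
      cue_offset_s = cue_t - t0,
      step_offsets_s = steps$timestamp_s - cue_t,
      pad_s = pad_s, baseline_window_s = baseline_window_s,
      channel_labels = stream$channel_labels,
      block = markers$block[i],
      context_pre = if (c0 < i0) stream$samples[, c0:(i0 - 1L), drop = FALSE],
      context_post = if (c1 > i1) stream$samples[, (i1 + 1L):c1, drop = FALSE]
    )
    epochs[[length(epochs)]]$anchor <- anchor
  }
  attr(epochs, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(trial_index = integer(0), reason = character(0))
  epochs
}
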