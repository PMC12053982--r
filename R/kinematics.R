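# Center-of-mass kinematics: per-axis velocity/acceleration from the CoM
# displacement trace and per-step / per-sequence / per-block summaries using
# the same cue/step segmentation as the EEG pipeline.

#' Per-axis CoM velocity
#'
#' Central differences in the interior, one-sided differences at the ends
#' (second-order accurate on smooth traces); same length as the input.
#'
#' @param trace a 3-channel `signal_stream` (or any channels x time stream).
#' @return matrix channels x time of velocities (m/s).
#' @export
com_velocity <- function(trace) {
  x <- trace$samples
  n <- ncol(x)
  if (n < 3L) stop_invalid("velocity needs at least 3 samples")
  fs <- trace$fs_hz
  v <- x
  v[, 2:(n - 1L)] <- (x[, 3:n, drop = FALSE] - x[, 1:(n - 2L), drop = FALSE]) * fs / 2
  v[, 1L] <- (x[, 2L] - x[, 1L]) * fs
  v[, n] <- (x[, n] - x[, n - 1L]) * fs
  v
}

#' Per-axis CoM acceleration
#'
#' Velocity of the velocity (twice-applied central differences).
#'
#' @inheritParams com_velocity
#' @return matrix channels x time (m/s^2).
#' @export
com_acceleration <- function(trace) {
  vtrace <- trace
  vtrace$samples <- com_velocity(trace)
  com_velocity(vtrace)
}

#' Per-step and per-sequence kinematics of one trial
#'
#' Splits the execution span into the same six half-open cue/step windows as
#' the EEG segmentation (cue->s1, ..., s5->s6) and summarizes per-axis mean
#' velocity, mean absolute velocity, and sequence-level peak speed (max
#' Euclidean norm).
#'
#' @param trace the CoM `signal_stream`.
#' @param markers a `marker_stream` on the same clock.
#' @param trial_index the trial to segment.
#' @param block optional block filter (needed when trial indices repeat
#'   across blocks).
#' @param n_steps expected steps (default 6).
#' @return a `sequence_kinematics` list: `trial_index`,
#'   `mean_velocity_mps` (3), `mean_abs_velocity_mps` (3),
#'   `peak_speed_mps`, `per_step_mean_velocity` (steps x 3),
#'   `per_step_mean_abs_velocity` (steps x 3), `step_durations_s`; or NULL
#'   with a message if markers are missing.
#' @export
segment_sequence <- function(trace, markers, trial_index, block = NA, n_steps = 6) {
  sel <- !is.na(markers$trial_index) & markers$trial_index == trial_index
  if (!is.na(block)) sel <- sel & !is.na(markers$block) & markers$block == block
  m <- markers[sel, ]
  cue <- m$timestamp_s[m$label == "CUE_GO"]
  steps <- sort(m$timestamp_s[grepl("^STEP_", m$label)])
  if (length(cue) != 1L || length(steps) < n_steps) {
    message(sprintf("trial %s skipped: incomplete markers", trial_index))
    return(NULL)
  }
  steps <- steps[seq_len(n_steps)]
  v <- com_velocity(trace)
  tt <- stream_times(trace)
  bounds <- c(cue, steps)
  per_step <- matrix(NA_real_, n_steps, 3L,
                     dimnames = list(NULL, trace$channel_labels))
  per_step_abs <- per_step
  dur <- diff(bounds)
  for (s in seq_len(n_steps)) {
    w <- tt >= bounds[s] & tt < bounds[s + 1L]
    if (!any(w)) next
    per_step[s, ] <- rowMeans(v[, w, drop = FALSE])
    per_step_abs[s, ] <- rowMeans(abs(v[, w, drop = FALSE]))
  }
  span <- tt >= bounds[1L] & tt < bounds[n_steps + 1L]
  vs <- v[, span, drop = FALSE]
  structure(list(
    trial_index = trial_index, block = block,
    mean_velocity_mps = rowMeans(vs),
    mean_abs_velocity_mps = rowMeans(abs(vs)),
    peak_speed_mps = max(sqrt(colSums(vs^2))),
    per_step_mean_velocity = per_step,
    per_step_mean_abs_velocity = per_step_abs,
    step_durations_s = dur
  ), class = "sequence_kinematics")
}

#' Per-block CoM velocity summary
#'
#' Mean and SD per axis of the sequence-level mean (and mean absolute)
#' velocities across a block's trials; by default restricted to accurate Go
#' trials, mirroring the behavioral analysis.
#'
#' @param per_trial list of `sequence_kinematics` (NULLs are dropped).
#' @param accurate optional logical vector marking which entries came from
#'   accurate trials; `NULL` keeps all.
#' @return list with per-axis `mean`, `sd`, `mean_abs`, `sd_abs`, and `n`.
#' @export
block_kinematics <- function(per_trial, accurate = NULL) {
  per_trial <- Filter(Negate(is.null), per_trial)
  if (!is.null(accurate)) per_trial <- per_trial[accurate[seq_along(per_trial)]]
  if (!length(per_trial)) stop_invalid("no valid trials to summarize")
  mv <- t(vapply(per_trial, `[[`, numeric(3), "mean_velocity_mps"))
  ma <- t(vapply(per_trial, `[[`, numeric(3), "mean_abs_velocity_mps"))
  list(mean = colMeans(mv), sd = apply(mv, 2L, stats::sd),
       mean_abs = colMeans(ma), sd_abs = apply(ma, 2L, stats::sd),
       n = length(per_trial))
}

#' Tidy per-step kinematics table for a whole session
#'
#' @param trace the CoM stream; `markers` the session markers.
#' @param markers a `marker_stream`.
#' @param participant id column value.
#' @param n_steps steps per sequence.
#' @return data.frame keyed (participant, block, trial, step, axis) with
#'   `mean_velocity_mps` and `mean_abs_velocity_mps`.
#' @export
kinematics_table <- function(trace, markers, participant = 1L, n_steps = 6) {
  cues <- markers[markers$label == "CUE_GO", ]
  rows <- list()
  for (i in seq_len(nrow(cues))) {
    sk <- segment_sequence(trace, markers, cues$trial_index[i],
                           block = cues$block[i], n_steps = n_steps)
    if (is.null(sk)) next
    rows[[length(rows) + 1L]] <- data.frame(
      participant = participant,
      block = cues$block[i],
      trial = cues$trial_index[i],
      step = rep(seq_len(n_steps), times = 3L),
      axis = rep(trace$channel_labels, each = n_steps),
      mean_velocity_mps = as.vector(sk$per_step_mean_velocity),
      mean_abs_velocity_mps = as.vector(sk$per_step_mean_abs_velocity))
  }
  do.call(rbind, rows)
}
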