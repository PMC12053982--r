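# Scoring of step responses against the scheduled sequence.
#
# Feedback mirrors the task script: "Good" for a fully correct sequence,
# "Too early!" when any response precedes the Go cue (or occurs at all on a
# NoGo trial), otherwise a list of the 1-based wrong step positions. Feedback
# about wrong steps is only given after all steps were completed.

#' Score one trial
#'
#' @param trial a trial row/list with `sequence` and `is_go`.
#' @param responses data.frame with columns `direction` (step codes) and
#'   `timestamp_s` (recording clock, seconds), time-ordered.
#' @param cue_time_s Go/NoGo cue time on the recording clock.
#' @return a `trial_result`: list with `trial`, `responses`,
#'   `per_step_correct`, `too_early`, `step_rts_ms`, `feedback`,
#'   `cue_time_s`. For too-early trials `per_step_correct` and
#'   `step_rts_ms` are empty.
#' @export
score_trial <- function(trial, responses, cue_time_s) {
  seq <- dance_sequence(trial$sequence)
  L <- length(seq)
  n <- if (is.null(responses)) 0L else nrow(responses)
  if (n > 1 && is.unsorted(responses$timestamp_s, strictly = FALSE)) {
    stop_invalid("responses must be time-ordered")
  }
  too_early <- if (isTRUE(trial$is_go)) {
    n > 0 && any(responses$timestamp_s < cue_time_s)
  } else {
    n > 0
  }
  if (too_early) {
    return(structure(list(trial = trial, responses = responses,
                          per_step_correct = logical(0), too_early = TRUE,
                          step_rts_ms = numeric(0), feedback = "Too early!",
                          cue_time_s = cue_time_s),
                     class = "trial_result"))
  }
  if (!isTRUE(trial$is_go)) {
    return(structure(list(trial = trial, responses = responses,
                          per_step_correct = logical(0), too_early = FALSE,
                          step_rts_ms = numeric(0), feedback = "",
                          cue_time_s = cue_time_s),
                     class = "trial_result"))
  }
  if (n < L) {
    stop_invalid("incomplete Go trial: %d responses for a %d-step sequence", n, L)
  }
  resp <- responses[seq_len(L), , drop = FALSE]
  correct <- toupper(resp$direction) == unclass(seq)
  rts <- step_response_times_raw(resp$timestamp_s, cue_time_s)
  feedback <- if (all(correct)) {
    "Good"
  } else {
    sprintf("Wrong steps: %s", paste(which(!correct), collapse = ","))
  }
  structure(list(trial = trial, responses = resp,
                 per_step_correct = correct, too_early = FALSE,
                 step_rts_ms = rts, feedback = feedback,
                 cue_time_s = cue_time_s),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s %s: %s\n",
              if (isTRUE(x$trial$is_go)) "Go" else "NoGo",
              x$trial$sequence, x$feedback))
  invisible(x)
}

# Step-level RTs from raw timestamps: first-step latency from the cue, then
# inter-step intervals (the standard DSP convention).
step_response_times_raw <- function(timestamps_s, cue_time_s) {
  if (length(timestamps_s) > 1 && any(diff(timestamps_s) <= 0)) {
    stop_invalid("response timestamps must be strictly increasing")
  }
  1000 * diff(c(cue_time_s, timestamps_s))
}

#' Step-level response times of a completed Go trial
#'
#' RT of step 1 is the latency from the Go cue; RTs of steps 2..L are
#' inter-step intervals, all in milliseconds.
#'
#' @param result a `trial_result` from [score_trial()] (complete Go trial,
#'   not too early).
#' @param cue_time_s optional cue time override; defaults to the one stored
#'   in the result.
#' @return numeric vector of length `sequence length`, all positive.
#' @export
step_response_times <- function(result, cue_time_s = result$cue_time_s) {
  if (isTRUE(result$too_early) || !isTRUE(result$trial$is_go)) {
    stop_invalid("step response times are defined only for completed Go trials")
  }
  step_response_times_raw(result$responses$timestamp_s, cue_time_s)
}

#' Block-level behavioral summary
#'
#' Mean step-level response time over accurate trials (all steps correct)
#' and the mistake percentage: trials with at least one wrong step or a
#' too-early start, as a percentage of Go trials. This is the end-of-block
#' feedback screen's content.
#'
#' @param results list of `trial_result`s for one block.
#' @return list `mean_rt_ms`, `mistake_pct`, `n_go`, `n_accurate`.
#' @export
block_summary <- function(results) {
  go <- Filter(function(r) isTRUE(r$trial$is_go), results)
  if (!length(go)) stop_invalid("no Go trials to summarize")
  completed <- Filter(function(r) !r$too_early, go)
  if (!length(completed)) stop_invalid("no completed Go trials to summarize")
  accurate <- Filter(function(r) all(r$per_step_correct), completed)
  if (!length(accurate)) stop_invalid("no accurate Go trials to summarize")
  rts <- unlist(lapply(accurate, `[[`, "step_rts_ms"))
  mistakes <- sum(vapply(go, function(r) {
    r$too_early || !all(r$per_step_correct)
  }, logical(1)))
  list(mean_rt_ms = mean(rts),
       mistake_pct = 100 * mistakes / length(go),
       n_go = length(go),
       n_accurate = length(accurate))
}

#' Tidy table of trial results
#'
#' @param results list of `trial_result`s.
#' @param block optional block number column.
#' @return data.frame keyed (block, trial_index) with sequence, go flag,
#'   feedback, per-step RT columns `rt1..rtL` and correctness flags
#'   `ok1..okL` (NA where undefined).
#' @export
results_table <- function(results, block = NA_integer_) {
  L <- max(vapply(results, function(r) nchar(as.character(r$trial$sequence)),
                  integer(1)))
  rows <- lapply(results, function(r) {
    rt <- ok <- rep(NA_real_, L)
    if (length(r$step_rts_ms)) rt[seq_along(r$step_rts_ms)] <- r$step_rts_ms
    if (length(r$per_step_correct)) ok[seq_along(r$per_step_correct)] <- as.numeric(r$per_step_correct)
    cbind(data.frame(block = block,
                     trial_index = r$trial$trial_index,
                     sequence = as.character(r$trial$sequence),
                     is_go = isTRUE(r$trial$is_go),
                     phase = if (!is.null(r$trial$phase)) r$trial$phase else NA,
                     too_early = r$too_early,
                     feedback = r$feedback),
          as.data.frame(setNames(as.list(rt), sprintf("rt%d", seq_len(L)))),
          as.data.frame(setNames(as.list(ok), sprintf("ok%d", seq_len(L)))))
  })
  do.call(rbind, rows)
}
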