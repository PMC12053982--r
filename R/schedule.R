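# Block and session scheduling for the Go/NoGo dance-mat DSP task.
#
# A block presents each of a participant's two sequences 24 times as Go
# trials plus 4 NoGo trials (92% Go / 8% NoGo), in seeded random order, with
# a 30-second break after trial 24. A session is 4 training blocks plus a
# 2-block test phase (one familiar, one novel block), separated by 3-minute
# breaks and a 10-minute break after block 4.

#' Timing template for one trial
#'
#' Durations of the trial phases, in milliseconds: the central fixation cross
#' (yellow), each successive stimulus placeholder, the blank interval before
#' the Go (blue) / NoGo (red) cue, and the NoGo waiting period.
#'
#' @param fixation_ms,stimulus_ms,pre_cue_ms,nogo_wait_ms positive integers (ms).
#' @return a `timing_template` list.
#' @export
timing_template <- function(fixation_ms = 1000, stimulus_ms = 750,
                            pre_cue_ms = 1500, nogo_wait_ms = 3000) {
  tmpl <- list(fixation_ms = fixation_ms, stimulus_ms = stimulus_ms,
               pre_cue_ms = pre_cue_ms, nogo_wait_ms = nogo_wait_ms)
  if (any(unlist(tmpl) <= 0)) stop_invalid("all timing durations must be > 0 ms")
  structure(tmpl, class = "timing_template")
}

#' Event timeline of a single trial
#'
#' Fixation at 0 ms, stimulus `i` (1-based) at `fixation + stimulus*(i-1)`,
#' and the Go/NoGo cue after a further pre-cue interval: for a 6-step trial
#' with default timing the cue falls at 1000 + 6*750 + 1500 = 7000 ms.
#'
#' @param trial one row of a block's `trials` data frame (or any list with
#'   `sequence` and `is_go`).
#' @param tmpl a [timing_template()].
#' @return data.frame with columns `event` and `onset_ms`.
#' @export
trial_timeline <- function(trial, tmpl = timing_template()) {
  seq <- dance_sequence(trial$sequence)
  L <- length(seq)
  events <- c("FIXATION",
              sprintf("STIMULUS_%d", seq_len(L)),
              if (isTRUE(trial$is_go)) "CUE_GO" else "CUE_NOGO")
  onsets <- c(0,
              tmpl$fixation_ms + tmpl$stimulus_ms * (seq_len(L) - 1L),
              tmpl$fixation_ms + tmpl$stimulus_ms * L + tmpl$pre_cue_ms)
  data.frame(event = events, onset_ms = onsets)
}

#' Schedule one practice block
#'
#' Builds `n_go_per_seq` Go trials for each sequence of the pair plus
#' `n_nogo` NoGo trials (which alternate between the two sequences), then
#' applies a single seeded shuffle of the whole trial multiset. Defaults give
#' 48 Go + 4 NoGo = 52 trials, a 92% Go frequency.
#'
#' @param pair list of two sequences as from [assign_participant_pair()].
#' @param n_go_per_seq Go repetitions per sequence (default 24).
#' @param n_nogo NoGo trial count (default 4).
#' @param seed integer; identical seeds give identical schedules.
#' @param phase `"training"` or `"test"`.
#' @param familiarity `"familiar"` or `"novel"`.
#' @param midblock_break_after trial count before the automatic mid-block
#'   break (default 24); `midblock_break_s` its duration in seconds.
#' @param midblock_break_s seconds.
#' @return a `block_schedule`: list with the `trials` data frame
#'   (`trial_index`, `sequence`, `is_go`, `phase`, `familiarity`) and break
#'   metadata.
#' @export
schedule_block <- function(pair, n_go_per_seq = 24, n_nogo = 4, seed,
                           phase = "training", familiarity = "familiar",
                           midblock_break_after = 24, midblock_break_s = 30) {
  stopifnot(n_go_per_seq >= 1, n_nogo >= 0)
  sA <- format(dance_sequence(pair[[1L]]))
  sB <- format(dance_sequence(pair[[2L]]))
  go <- data.frame(
    sequence = rep(c(sA, sB), each = n_go_per_seq),
    is_go = TRUE
  )
  nogo <- if (n_nogo > 0) {
    data.frame(sequence = rep(c(sA, sB), length.out = n_nogo), is_go = FALSE)
  } else {
    data.frame(sequence = character(0), is_go = logical(0))
  }
  trials <- rbind(go, nogo)
  ord <- with_seed(seed, sample.int(nrow(trials)))
  trials <- trials[ord, , drop = FALSE]
  trials$trial_index <- seq_len(nrow(trials))
  trials$phase <- phase
  trials$familiarity <- familiarity
  rownames(trials) <- NULL
  trials <- trials[, c("trial_index", "sequence", "is_go", "phase", "familiarity")]
  structure(
    list(trials = trials, midblock_break_after = midblock_break_after,
         midblock_break_s = midblock_break_s, seed = as.integer(seed)),
    class = "block_schedule"
  )
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> %d trials (%d Go, %d NoGo), seed %d\n",
              nrow(x$trials), sum(x$trials$is_go), sum(!x$trials$is_go), x$seed))
  invisible(x)
}

#' Schedule a full session
#'
#' `n_training` training blocks on the participant's pair followed by a test
#' phase of `n_test` blocks alternating familiar (trained pair) and novel
#' (untrained pair) material; test-block order is counterbalanced by
#' participant parity (even index: familiar first). Break structure: 30 s
#' mid-block, 180 s between blocks, 600 s after `long_break_after_block`.
#'
#' @param pair trained sequence pair; `novel_pair` an untrained pair for the
#'   test phase (a warning is raised if it collides with any rotation of the
#'   trained pair).
#' @param novel_pair list of two sequences.
#' @param n_training,n_test block counts (defaults 4 and 2).
#' @param participant_index non-negative integer, controls test order.
#' @param seed integer; per-block seeds are derived as `seed + block number`.
#' @param n_go_per_seq,n_nogo per-block trial counts, see [schedule_block()].
#' @param interblock_break_s,long_break_after_block,long_break_s break structure.
#' @return a `session_schedule`: list of `blocks` plus break metadata. With
#'   defaults the session holds 6 blocks x 48 Go trials x 6 steps = 1728 steps.
#' @export
schedule_session <- function(pair, novel_pair, n_training = 4, n_test = 2,
                             participant_index = 0, seed,
                             n_go_per_seq = 24, n_nogo = 4,
                             interblock_break_s = 180,
                             long_break_after_block = 4, long_break_s = 600) {
  stopifnot(n_training >= 1, n_test >= 0)
  trained <- unlist(lapply(0:3, function(k) {
    c(format(rotate_sequence(pair[[1L]], k)), format(rotate_sequence(pair[[2L]], k)))
  }))
  novel_strs <- vapply(novel_pair, function(s) format(dance_sequence(s)), character(1))
  if (any(novel_strs %in% trained)) {
    warning(sprintf("novel pair overlaps the trained counterbalance set: %s",
                    paste(intersect(novel_strs, trained), collapse = ", ")),
            call. = FALSE)
  }
  blocks <- list()
  for (b in seq_len(n_training)) {
    blocks[[b]] <- schedule_block(pair, n_go_per_seq, n_nogo, seed = seed + b,
                                  phase = "training", familiarity = "familiar")
  }
  familiar_first <- as.integer(participant_index) %% 2L == 0L
  test_fam <- rep(if (familiar_first) c("familiar", "novel") else c("novel", "familiar"),
                  length.out = n_test)
  for (i in seq_len(n_test)) {
    b <- n_training + i
    use_pair <- if (test_fam[i] == "familiar") pair else novel_pair
    blocks[[b]] <- schedule_block(use_pair, n_go_per_seq, n_nogo, seed = seed + b,
                                  phase = "test", familiarity = test_fam[i])
  }
  structure(
    list(blocks = blocks, interblock_break_s = interblock_break_s,
         long_break_after_block = long_break_after_block,
         long_break_s = long_break_s,
         participant_index = as.integer(participant_index),
         seed = as.integer(seed)),
    class = "session_schedule"
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %d blocks (%d training), %d Go steps total\n",
              length(x$blocks),
              sum(vapply(x$blocks, function(b) unique(b$trials$phase) == "training", logical(1))),
              session_step_count(x)))
  invisible(x)
}

#' Total number of Go steps scheduled in a session
#'
#' Sum over blocks of (Go trials x sequence length); the default session
#' yields 1728 steps.
#'
#' @param session a `session_schedule`.
#' @return integer step count.
#' @export
session_step_count <- function(session) {
  sum(vapply(session$blocks, function(b) {
    go <- b$trials[b$trials$is_go, , drop = FALSE]
    sum(nchar(go$sequence))
  }, numeric(1)))
}

#' Flatten a session schedule to one trial table
#'
#' @param session a `session_schedule`.
#' @return data.frame with a `block` column prepended to each block's trials.
#' @export
session_trials <- function(session) {
  do.call(rbind, lapply(seq_along(session$blocks), function(b) {
    cbind(block = b, session$blocks[[b]]$trials)
  }))
}
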