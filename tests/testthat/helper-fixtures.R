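# Shared fixtures: small schedules and simulated sessions built in code.

base_pair <- function(participant = 0) {
  cb <- build_counterbalance_set("LRUDRL", "RULURD")
  assign_participant_pair(cb, participant)
}

# A session schedule with an arbitrary list of blocks (bypasses the
# training/test bookkeeping when only timing/marker structure matters).
bare_session <- function(blocks) {
  structure(list(blocks = blocks, interblock_break_s = 180,
                 long_break_after_block = 4, long_break_s = 600,
                 participant_index = 0L, seed = 0L),
            class = "session_schedule")
}

# Small single-block simulated session used by several modules' tests.
small_session <- function(n_go_per_seq = 6, n_nogo = 1, n_channels = 2,
                          seed = 42, ...) {
  blk <- schedule_block(base_pair(), n_go_per_seq = n_go_per_seq,
                        n_nogo = n_nogo, seed = seed)
  simulate_session(bare_session(list(blk)),
                   sim_params(n_channels = n_channels, seed = seed, ...))
}

# Manually constructed responses for scoring tests.
make_responses <- function(directions, times) {
  data.frame(direction = directions, timestamp_s = times)
}
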