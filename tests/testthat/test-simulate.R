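# Synthetic-session generator: behavior, EEG, CoM, markers, determinism.

test_that("zero decay and noise give constant step RTs at asymptote + gain", {
  blk <- schedule_block(base_pair(), n_go_per_seq = 3, n_nogo = 0, seed = 1)
  p <- sim_params(rt_decay_per_trial = 0, rt_noise_sd_ms = 0, error_prob = 0,
                  seed = 1)
  beh <- simulate_behavior(bare_session(list(blk)), p)
  rts <- unlist(lapply(beh[[1]], `[[`, "step_rts_ms"))
  expect_equal(rts, rep(p$rt_asymptote_ms + p$rt_gain_ms, 6 * 6),
               ignore_attr = TRUE)
})

test_that("zero error probability yields all-'Good' feedback", {
  blk <- schedule_block(base_pair(), n_go_per_seq = 4, n_nogo = 1, seed = 2)
  beh <- simulate_behavior(bare_session(list(blk)), sim_params(error_prob = 0, seed = 2))
  go <- Filter(function(r) isTRUE(r$trial$is_go), beh[[1]])
  expect_true(all(vapply(go, `[[`, character(1), "feedback") == "Good"))
})

test_that("exponential RT curve parameters are recovered from 192 trials", {
  pair <- base_pair()
  blks <- lapply(1:4, function(b) schedule_block(pair, n_nogo = 0, seed = 10 + b))
  p <- sim_params(error_prob = 0, seed = 11)
  beh <- simulate_behavior(bare_session(blks), p)
  fit <- fit_rt_curve(beh)
  expect_equal(fit$n_trials, 192L)
  expect_lt(abs(fit$decay_per_trial - p$rt_decay_per_trial) / p$rt_decay_per_trial, 0.2)
  expect_lt(abs(fit$asymptote_ms - p$rt_asymptote_ms) / p$rt_asymptote_ms, 0.2)
  expect_lt(abs(fit$gain_ms - p$rt_gain_ms) / p$rt_gain_ms, 0.2)
})

test_that("marker structure: one cue per trial, steps only on completed Go trials", {
  ss <- small_session(n_go_per_seq = 4, n_nogo = 2)
  m <- ss$markers
  trials <- ss$schedule$blocks[[1]]$trials
  expect_equal(sum(m$label == "CUE_GO"), sum(trials$is_go))
  expect_equal(sum(m$label == "CUE_NOGO"), sum(!trials$is_go))
  expect_equal(sum(grepl("^STEP_", m$label)), sum(trials$is_go) * 6L)
  expect_equal(sum(m$label == "BLOCK_START"), 1L)
  expect_false(is.unsorted(m$timestamp_s))
})

test_that("identical seeds give bit-identical synthetic sessions", {
  a <- small_session(seed = 77)
  b <- small_session(seed = 77)
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$kinematics$samples, b$kinematics$samples)
  expect_identical(as.data.frame(a$markers), as.data.frame(b$markers))
  c_ <- small_session(seed = 78)
  expect_false(identical(a$eeg$samples, c_$eeg$samples))
})

test_that("theta amplitude is scaled by sqrt(1 + ERDS/100) inside step windows", {
  blk <- schedule_block(base_pair(), n_go_per_seq = 1, n_nogo = 0, seed = 3)
  p <- sim_params(n_channels = 1, pink_noise_sd_uv = 0, error_prob = 0,
                  rt_noise_sd_ms = 0, erds_per_step_pct = rep(100, 6), seed = 3)
  ss <- simulate_session(bare_session(list(blk)), p)
  r <- ss$behavior[[1]][[1]]
  tt <- stream_times(ss$eeg)
  inside <- tt > r$cue_time_s + 0.05 & tt < r$responses$timestamp_s[6] - 0.05
  before <- tt > r$cue_time_s - 1.0 & tt < r$cue_time_s - 0.05
  ratio <- max(abs(ss$eeg$samples[1, inside])) / max(abs(ss$eeg$samples[1, before]))
  expect_equal(ratio, sqrt(2), tolerance = 0.01)
})

test_that("no modulation and no noise gives a constant-amplitude sinusoid", {
  blk <- schedule_block(base_pair(), n_go_per_seq = 1, n_nogo = 0, seed = 4)
  p <- sim_params(n_channels = 1, pink_noise_sd_uv = 0, rt_noise_sd_ms = 0,
                  error_prob = 0, erds_per_step_pct = rep(0, 6), seed = 4)
  ss <- simulate_session(bare_session(list(blk)), p)
  x <- ss$eeg$samples[1, ]
  expect_equal(max(abs(x)), p$baseline_theta_amp_uv, tolerance = 1e-3)
  # RMS of a sinusoid
  expect_equal(stats::sd(x), p$baseline_theta_amp_uv / sqrt(2), tolerance = 1e-2)
})

test_that("an isolated step's CoM excursion peaks at 1.5 d / T per axis", {
  blk <- schedule_block(base_pair(), n_go_per_seq = 1, n_nogo = 0, seed = 5)
  # slow out-of-curve RTs so steps are far apart and the full ramp is used
  p <- sim_params(rt_asymptote_ms = 1000, rt_gain_ms = 0, rt_noise_sd_ms = 0,
                  error_prob = 0, n_channels = 1, pink_noise_sd_uv = 0, seed = 5)
  ss <- simulate_session(bare_session(list(blk)), p)
  v <- com_velocity(ss$kinematics)
  expected_peak <- 1.5 * 0.3 / p$com_ramp_s
  expect_equal(max(abs(v[1, ])), expected_peak, tolerance = 0.02)
  # displacement returns to centre after the sequence
  expect_lt(max(abs(ss$kinematics$samples[, ncol(ss$kinematics$samples)])), 1e-9)
})

test_that("per-axis velocity sign matches the step direction convention", {
  p <- sim_params()
  for (d in c("L", "R", "U", "D")) {
    beh <- list(list(structure(list(
      trial = list(trial_index = 1L, sequence = "LRUDRL", is_go = TRUE),
      responses = data.frame(direction = d, timestamp_s = 3.0),
      per_step_correct = TRUE, too_early = FALSE, step_rts_ms = 500,
      feedback = "Good", cue_time_s = 2.5), class = "trial_result")))
    attr(beh, "t_end_s") <- 5
    com <- simulate_com(beh, p)
    v <- com_velocity(com)
    tt <- stream_times(com)
    approach <- tt > 2.7 & tt < 3.0   # outbound leg
    truth <- p$com_step_displacement_m[[d]]
    for (ax in 1:2) {
      if (truth[ax] != 0) expect_equal(sign(mean(v[ax, approach])), sign(truth[ax]))
    }
  }
})
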