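# CoM velocity, segmentation and block summaries.

test_that("velocity of constant and linear displacement is exact", {
  fs <- 100
  const <- signal_stream("com", c("x", "y", "z"), fs, 0, matrix(2, 3, 500))
  expect_equal(com_velocity(const), matrix(0, 3, 500), ignore_attr = TRUE)
  t <- (0:499) / fs
  ramp <- signal_stream("com", c("x", "y", "z"), fs, 0,
                        rbind(0.2 * t, -0.1 * t, 0 * t))
  v <- com_velocity(ramp)
  expect_equal(v[1, ], rep(0.2, 500), tolerance = 1e-10)
  expect_equal(v[2, ], rep(-0.1, 500), tolerance = 1e-10)
  expect_error(com_velocity(signal_stream("com", "x", fs, 0, matrix(0, 1, 2))),
               "at least 3")
})

test_that("smoothstep excursion peak velocity is within 2% of closed form", {
  fs <- 100
  T_ <- 0.4
  D <- 0.3
  t <- (0:199) / fs
  u <- pmin(pmax((t - 0.5) / T_, 0), 1)
  x <- D * u^2 * (3 - 2 * u)
  tr <- signal_stream("com", c("x", "y", "z"), fs, 0, rbind(x, 0 * t, 0 * t))
  v <- com_velocity(tr)
  expect_equal(max(v[1, ]), 1.5 * D / T_, tolerance = 0.02)
})

test_that("differentiate-then-integrate recovers a smooth displacement", {
  fs <- 100
  t <- (0:499) / fs
  x <- 0.1 * sin(2 * pi * 0.5 * t)
  tr <- signal_stream("com", c("x", "y", "z"), fs, 0, rbind(x, x, x))
  v <- com_velocity(tr)[1, ]
  # cumulative trapezoid
  xi <- c(0, cumsum((v[-1] + v[-length(v)]) / 2)) / fs
  expect_equal(xi, x - x[1], tolerance = 1e-3)
})

test_that("segmentation attributes motion to the right axis and windows", {
  blk <- schedule_block(base_pair(), n_go_per_seq = 2, n_nogo = 0, seed = 12)
  p <- sim_params(n_channels = 1, pink_noise_sd_uv = 0, error_prob = 0,
                  rt_noise_sd_ms = 0, seed = 12)
  ss <- simulate_session(bare_session(list(blk)), p)
  cues <- ss$markers[ss$markers$label == "CUE_GO", ]
  sk <- segment_sequence(ss$kinematics, ss$markers, cues$trial_index[1],
                         block = cues$block[1])
  expect_s3_class(sk, "sequence_kinematics")
  expect_equal(dim(sk$per_step_mean_velocity), c(6L, 3L))
  seqs <- ss$schedule$blocks[[1]]$trials
  # step 1's window (cue -> step 1) holds only that step's outbound leg, so
  # its signed mean velocity matches the direction convention; later windows
  # also carry the previous step's return leg
  for (i in seq_len(nrow(cues))) {
    ski <- segment_sequence(ss$kinematics, ss$markers, cues$trial_index[i],
                            block = cues$block[i])
    seq_str <- seqs$sequence[seqs$trial_index == cues$trial_index[i]]
    d1 <- p$com_step_displacement_m[[substr(seq_str, 1, 1)]]
    ax <- which.max(abs(d1[1:2]))
    expect_equal(unname(sign(ski$per_step_mean_velocity[1, ax])), sign(d1[ax]))
    expect_gt(abs(ski$per_step_mean_velocity[1, ax]),
              abs(ski$per_step_mean_velocity[1, 3 - ax]))
  }
})

test_that("zero motion gives all-zero sequence kinematics", {
  fs <- 100
  tr <- signal_stream("com", c("x", "y", "z"), fs, 0, matrix(0, 3, 20 * fs))
  m <- marker_stream(c("CUE_GO", sprintf("STEP_%d", 1:6)),
                     c(3, 3 + (1:6) * 0.5), rep(1L, 7))
  sk <- segment_sequence(tr, m, 1L)
  expect_equal(unname(sk$mean_velocity_mps), c(0, 0, 0))
  expect_equal(sk$peak_speed_mps, 0)
})

test_that("whole-sequence mean is the duration-weighted mean of step means", {
  ss <- small_session(n_go_per_seq = 2, n_nogo = 0, seed = 13)
  cues <- ss$markers[ss$markers$label == "CUE_GO", ]
  sk <- segment_sequence(ss$kinematics, ss$markers, cues$trial_index[1],
                         block = cues$block[1])
  w <- sk$step_durations_s / sum(sk$step_durations_s)
  recon <- colSums(sk$per_step_mean_velocity * w)
  expect_equal(unname(recon), unname(sk$mean_velocity_mps), tolerance = 0.05)
})

test_that("missing markers skip the trial with a message", {
  fs <- 100
  tr <- signal_stream("com", c("x", "y", "z"), fs, 0, matrix(0, 3, 1000))
  m <- marker_stream(c("CUE_GO", "STEP_1"), c(3, 3.5), c(1L, 1L))
  expect_message(out <- segment_sequence(tr, m, 1L), "skipped")
  expect_null(out)
})

test_that("block kinematics averages valid trials; identical trials give SD 0", {
  mk <- function() structure(list(mean_velocity_mps = c(0.1, 0.2, 0),
                                  mean_abs_velocity_mps = c(0.1, 0.2, 0)),
                             class = "sequence_kinematics")
  bk <- block_kinematics(list(mk(), mk(), NULL))
  expect_equal(bk$n, 2L)
  expect_equal(unname(bk$mean), c(0.1, 0.2, 0))
  expect_equal(unname(bk$sd), c(0, 0, 0))
  # accuracy filter drops flagged entries
  bk2 <- block_kinematics(list(mk(), mk()), accurate = c(TRUE, FALSE))
  expect_equal(bk2$n, 1L)
  expect_error(block_kinematics(list(NULL)), "no valid trials")
})

test_that("kinematics table is keyed participant/block/trial/step/axis", {
  ss <- small_session(n_go_per_seq = 2, n_nogo = 1, seed = 14)
  tab <- kinematics_table(ss$kinematics, ss$markers, participant = 9L)
  expect_equal(nrow(tab), 4 * 6 * 3)
  expect_setequal(unique(tab$axis), c("x", "y", "z"))
  expect_true(all(tab$participant == 9L))
})
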