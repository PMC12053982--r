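# Preprocessing, Morlet theta power, time normalization, ERD/S.

make_stream <- function(x, fs = 500, labels = paste0("ch", seq_len(nrow(x)))) {
  signal_stream("eeg", labels, fs, 0, x)
}

sin_epoch <- function(freq = 6, amp = 10, dur = 5, fs = 500, phase = 0,
                      steps = (1:6) * 0.7) {
  t <- (seq_len(dur * fs) - 1) / fs
  epoch(1L, matrix(amp * sin(2 * pi * freq * t + phase), 1), fs, 0,
        cue_offset_s = 0.3, step_offsets_s = steps, channel_labels = "ch1")
}

test_that("bandpass keeps 6 Hz, rejects 50 Hz and DC", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  mk <- function(f) make_stream(matrix(sin(2 * pi * f * t), 1), fs)
  mid <- seq(2 * fs, 8 * fs)   # avoid filter edge transients
  g6 <- max(abs(bandpass(mk(6))$samples[1, mid]))
  expect_equal(g6, 1, tolerance = 0.01)
  g50 <- max(abs(bandpass(mk(50))$samples[1, mid]))
  expect_lt(20 * log10(g50), -20)
  const <- bandpass(make_stream(matrix(1, 1, 10 * fs), fs))
  # the 0.3 Hz high-pass transient decays with ~0.5 s time constant
  expect_lt(max(abs(const$samples[1, seq(4 * fs, 6 * fs)])), 5e-3)
  expect_error(bandpass(make_stream(matrix(0, 1, 100), fs = 50)), "too low")
})

test_that("average reference zeroes channel sums and removes common offsets", {
  x <- rbind(sin(1:100), -sin(1:100))
  expect_equal(average_reference(make_stream(x, 100))$samples, x,
               ignore_attr = TRUE)
  y <- x + 5
  ref <- average_reference(make_stream(y, 100))
  expect_equal(colSums(ref$samples), rep(0, 100), tolerance = 1e-12)
  expect_error(average_reference(make_stream(x[1, , drop = FALSE], 100)),
               "at least 2")
})

test_that("artifact hook is identity for 'none', delegates to callables, and logs", {
  s <- make_stream(matrix(rnorm(200), 2), 100)
  out <- artifact_removal_hook(s, "none")
  expect_identical(out$samples, s$samples)
  zeroer <- function(st) { st$samples[1, ] <- 0; st }
  z <- artifact_removal_hook(s, zeroer)
  expect_equal(z$samples[1, ], rep(0, 100))
  expect_equal(z$samples[2, ], s$samples[2, ])
  log <- attr(z, "artifact_log")
  expect_equal(log[[1]]$method, "injected")
  expect_error(artifact_removal_hook(s, "wavelet-magic"), "unknown")
})

test_that("stationary sinusoid gives flat band power after trimming", {
  for (phase in c(0, 1.1, 2.5)) {
    tp <- morlet_theta_power(sin_epoch(phase = phase))
    p <- tp$power[1, ]
    expect_lt(stats::sd(p) / mean(p), 0.05)
  }
})

test_that("amplitude step of sqrt(2) doubles band power", {
  fs <- 500
  t <- (0:(6 * fs - 1)) / fs
  amp <- ifelse(t < 3, 10, 10 * sqrt(2))
  ep <- epoch(1L, matrix(amp * sin(2 * pi * 6 * t), 1), fs, 0,
              cue_offset_s = 0.3, step_offsets_s = (1:6) * 0.9,
              channel_labels = "ch1")
  tp <- morlet_theta_power(ep)
  lo <- mean(tp$power[1, tp$times_s > 0 & tp$times_s < 2.2])
  hi <- mean(tp$power[1, tp$times_s > 3.2 & tp$times_s < 5.2])
  expect_equal(hi / lo, 2, tolerance = 0.05)
})

test_that("zero signal gives zero power and short epochs error", {
  fs <- 500
  ep <- epoch(1L, matrix(0, 1, 3 * fs), fs, 0, cue_offset_s = 0.3,
              step_offsets_s = (1:6) * 0.4, channel_labels = "ch1")
  expect_equal(max(morlet_theta_power(ep)$power), 0)
  tiny <- epoch(1L, matrix(0, 1, 50), fs, 0, cue_offset_s = 0.02,
                step_offsets_s = (1:6) * 0.01, pad_s = 0,
                channel_labels = "ch1")
  expect_error(morlet_theta_power(tiny), "too short")
})

test_that("baseline power is the mean over the pre-cue window", {
  tp <- morlet_theta_power(sin_epoch())
  b <- baseline_power(tp)
  manual <- mean(tp$power[1, tp$times_s >= -0.2 & tp$times_s < 0])
  expect_equal(unname(b), manual)
  expect_error(baseline_power(tp, c(-9, -8)), "no samples")
})

test_that("time normalization emits exactly n_bins, constant in constant out", {
  tp <- morlet_theta_power(sin_epoch())
  norm <- time_normalize(tp)
  expect_equal(dim(norm), c(1L, 300L))
  expect_equal(dim(time_normalize(tp, mode = "global")), c(1L, 300L))
  expect_equal(unname(time_normalize(rep(4.2, 1234), mode = "global")),
               rep(4.2, 300))
})

test_that("3000-sample global binning averages consecutive blocks of 10", {
  x <- seq_len(3000)
  got <- time_normalize(x, mode = "global")
  expected <- vapply(0:299, function(b) mean(x[(10 * b + 1):(10 * b + 10)]),
                     numeric(1))
  expect_equal(unname(got), expected)
})

test_that("global binning matches the explicit index-window oracle", {
  # oracle: bin b (0-based) of N samples in B bins averages samples
  # floor(N*b/B)+1 .. floor(N*(b+1)/B)
  oracle <- function(x, B) {
    N <- length(x)
    vapply(0:(B - 1), function(b) {
      mean(x[(floor(N * b / B) + 1):floor(N * (b + 1) / B)])
    }, numeric(1))
  }
  set.seed(314)
  for (i in 1:200) {
    N <- sample(300:3000, 1)
    x <- rnorm(N)
    expect_equal(unname(time_normalize(x, mode = "global")), oracle(x, 300))
  }
})

test_that("binning conserves the series mean when counts divide evenly", {
  x <- rnorm(1500)
  expect_equal(mean(time_normalize(x, mode = "global")), mean(x))
})

test_that("step bins are six means of 50 consecutive values", {
  expect_equal(unname(step_bins(rep(3.3, 300))), rep(3.3, 6))
  expect_equal(unname(step_bins(0:299)),
               c(24.5, 74.5, 124.5, 174.5, 224.5, 274.5))
  expect_error(step_bins(1:299), "6 step bins")
})

test_that("ERD/S formula gives the analytic cases and is scale-invariant", {
  expect_equal(erds_percent(2, 1), 100)
  expect_equal(erds_percent(1, 1), 0)
  expect_equal(erds_percent(0.5, 1), -50)
  expect_error(erds_percent(1, 0), "baseline")
  for (k in c(1e-6, 0.5, 3, 1e4)) {
    expect_equal(erds_percent(k * 1.7, k * 0.9), erds_percent(1.7, 0.9))
  }
})

test_that("per-step ERD/S is recovered from a clean modulated epoch set", {
  # noise-free session: only wavelet smearing separates recovery from truth
  blk <- schedule_block(base_pair(), n_go_per_seq = 5, n_nogo = 0, seed = 6)
  p <- sim_params(n_channels = 2, pink_noise_sd_uv = 0, error_prob = 0, seed = 6)
  ss <- simulate_session(bare_session(list(blk)), p)
  eps <- extract_sequence_epochs(ss$eeg, ss$markers)
  tab <- erds_table(eps)
  rec <- stats::aggregate(erds_pct ~ step, tab, mean)$erds_pct
  expect_lt(mean(abs(rec - p$erds_per_step_pct)), 10)
})

test_that("zero modulation recovers a near-zero profile", {
  blk <- schedule_block(base_pair(), n_go_per_seq = 3, n_nogo = 0, seed = 8)
  p <- sim_params(n_channels = 2, pink_noise_sd_uv = 0, error_prob = 0,
                  erds_per_step_pct = rep(0, 6), seed = 8)
  ss <- simulate_session(bare_session(list(blk)), p)
  eps <- extract_sequence_epochs(ss$eeg, ss$markers)
  tab <- erds_table(eps)
  expect_lt(max(abs(tab$erds_pct)), 5)
})

test_that("erds_profile returns a tidy per-channel per-step frame", {
  ss <- small_session(n_go_per_seq = 2, n_nogo = 0, n_channels = 3)
  eps <- extract_sequence_epochs(ss$eeg, ss$markers)
  prof <- erds_profile(eps[[1]])
  expect_equal(nrow(prof), 3 * 6)
  expect_setequal(names(prof),
                  c("trial_index", "block", "channel", "step", "erds_pct"))
  expect_true(all(prof$erds_pct > -100))
})
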