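# Synthetic multimodal session generator with known ground truth.
#
# Behavior follows an exponential learning curve over Go trials,
#   RT(t) = asymptote + gain * exp(-decay * t) + Normal(0, sd),  truncated > 50 ms,
# each step wrong independently with a fixed error probability. EEG channels
# carry a theta oscillation whose amplitude during the execution window of
# step s is scaled by sqrt(1 + ERDS_s/100) — power-correct, so the programmed
# per-step ERD/S is exact in expectation — plus seeded 1/f noise. The CoM
# trace is a sum of cubic smoothstep out-and-back excursions centred on each
# response. All three streams share one clock and a common marker stream.

#' Ground-truth simulation parameters
#'
#' Defaults describe a plausible single-participant session: RT curve
#' calibrated so the mean step RT over 192 learning trials is ~358 ms,
#' 5% step errors, a 6 Hz / 10 uV theta rhythm over 22 channels at 500 Hz,
#' per-step ERD/S spanning -40% (desynchronization) to +35%
#' (synchronization), and 1/f noise giving an in-band SNR near 3.
#'
#' @param rt_asymptote_ms,rt_gain_ms,rt_decay_per_trial,rt_noise_sd_ms RT
#'   learning-curve parameters (ms; decay per Go trial, >= 0).
#' @param error_prob per-step error probability in `[0, 1]`.
#' @param eeg_fs_hz,kin_fs_hz,n_channels stream geometry.
#' @param theta_freq_hz oscillation frequency in `[4, 8]`.
#' @param baseline_theta_amp_uv baseline oscillation amplitude (uV).
#' @param erds_per_step_pct 6 programmed ERD/S percentages, each > -100.
#' @param pink_noise_sd_uv total SD of the 1/f noise (uV).
#' @param com_step_displacement_m named list mapping step codes U/D/L/R to
#'   `(dx, dy, dz)` excursions in metres (x = left-right, y = forward-back,
#'   z = vertical).
#' @param com_ramp_s one-way smoothstep leg duration (seconds).
#' @param seed integer master seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(rt_asymptote_ms = 300, rt_gain_ms = 227,
                       rt_decay_per_trial = 0.02, rt_noise_sd_ms = 50,
                       error_prob = 0.05,
                       eeg_fs_hz = 500, kin_fs_hz = 100, n_channels = 22,
                       theta_freq_hz = 6, baseline_theta_amp_uv = 10,
                       erds_per_step_pct = c(-40, -25, -10, 5, 20, 35),
                       pink_noise_sd_uv = 7,
                       com_step_displacement_m = list(
                         U = c(0, 0.3, 0.02), D = c(0, -0.3, 0.02),
                         L = c(-0.3, 0, 0.02), R = c(0.3, 0, 0.02)),
                       com_ramp_s = 0.4,
                       seed = 1L) {
  stopifnot(rt_decay_per_trial >= 0, error_prob >= 0, error_prob <= 1,
            eeg_fs_hz > 0, kin_fs_hz > 0,
            theta_freq_hz >= 4, theta_freq_hz <= 8,
            all(erds_per_step_pct > -100))
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate behavioral responses for a schedule
#'
#' Walks the session's trials on a continuous recording clock (the rest
#' breaks stay in the schedule metadata; the simulated timeline runs trials
#' back to back with a 1 s feedback interval). Go-trial step RTs follow the
#' exponential learning curve over the cumulative Go-trial counter; each
#' step is wrong with `error_prob` (replaced by a random other direction).
#'
#' @param schedule a `session_schedule` or single `block_schedule`.
#' @param params a [sim_params()].
#' @param tmpl a [timing_template()].
#' @return list of blocks, each a list of `trial_result`s (with
#'   `cue_time_s` on the session clock); attribute `t_end_s` is the clock
#'   time after the last trial.
#' @export
simulate_behavior <- function(schedule, params, tmpl = timing_template()) {
  blocks <- if (inherits(schedule, "session_schedule")) schedule$blocks else list(schedule)
  with_seed(params$seed, {
    t_cursor <- 1.0      # lead-in before the first trial
    go_counter <- 0L
    out <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      trials <- blocks[[b]]$trials
      res <- vector("list", nrow(trials))
      for (i in seq_len(nrow(trials))) {
        tr <- as.list(trials[i, ])
        tl <- trial_timeline(tr, tmpl)
        cue_t <- t_cursor + tl$onset_ms[nrow(tl)] / 1000
        if (tr$is_go) {
          seq_steps <- unclass(dance_sequence(tr$sequence))
          L <- length(seq_steps)
          mu <- params$rt_asymptote_ms +
            params$rt_gain_ms * exp(-params$rt_decay_per_trial * go_counter)
          rts <- mu + stats::rnorm(L, 0, params$rt_noise_sd_ms)
          rts <- pmax(rts, 50)
          wrong <- stats::runif(L) < params$error_prob
          dirs <- seq_steps
          for (k in which(wrong)) {
            dirs[k] <- sample(setdiff(unname(STEP_DIRECTIONS), seq_steps[k]), 1L)
          }
          responses <- data.frame(direction = dirs,
                                  timestamp_s = cue_t + cumsum(rts) / 1000)
          res[[i]] <- score_trial(tr, responses, cue_t)
          go_counter <- go_counter + 1L
          t_cursor <- responses$timestamp_s[L] + 1.0
        } else {
          res[[i]] <- score_trial(tr, NULL, cue_t)
          t_cursor <- cue_t + tmpl$nogo_wait_ms / 1000 + 1.0
        }
      }
      out[[b]] <- res
    }
    attr(out, "t_end_s") <- t_cursor
    out
  })
}

# Markers for a simulated behavior set: BLOCK_START, one cue per trial, one
# STEP_k per response of completed Go trials.
behavior_markers <- function(behavior) {
  rows <- list()
  for (b in seq_along(behavior)) {
    first_cue <- behavior[[b]][[1L]]$cue_time_s
    rows[[length(rows) + 1L]] <- data.frame(
      label = "BLOCK_START", timestamp_s = first_cue - 7.0,
      trial_index = NA_integer_, block = b)
    for (r in behavior[[b]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = if (isTRUE(r$trial$is_go)) "CUE_GO" else "CUE_NOGO",
        timestamp_s = r$cue_time_s, trial_index = r$trial$trial_index, block = b)
      if (isTRUE(r$trial$is_go) && !r$too_early && nrow(r$responses)) {
        rows[[length(rows) + 1L]] <- data.frame(
          label = sprintf("STEP_%d", seq_len(nrow(r$responses))),
          timestamp_s = r$responses$timestamp_s,
          trial_index = r$trial$trial_index, block = b)
      }
    }
  }
  m <- do.call(rbind, rows)
  m <- m[order(m$timestamp_s), ]
  rownames(m) <- NULL
  marker_stream(m$label, m$timestamp_s, m$trial_index, m$block)
}

# Seeded 1/f (pink) noise of length n: white Gaussian spectrum shaped by
# 1/sqrt(f) above f_min, flat below, rescaled to the target SD.
pink_noise <- function(n, fs, sd, f_min = 0.5) {
  if (sd <= 0) return(rep(0, n))
  nfft <- stats::nextn(n, 2L)
  f <- c(0, seq_len(nfft / 2), rev(seq_len(nfft / 2 - 1L))) * fs / nfft
  shape <- 1 / sqrt(pmax(f, f_min))
  shape[1L] <- 0
  spec <- stats::fft(stats::rnorm(nfft)) * shape
  x <- Re(stats::fft(spec, inverse = TRUE) / nfft)[seq_len(n)]
  x * sd / stats::sd(x)
}

#' Simulate the EEG stream and its marker stream
#'
#' Each channel is `amp(t) * baseline_theta_amp * sin(2 pi f t + phi_ch)`
#' plus independent 1/f noise. `amp(t)` is 1 everywhere except during the
#' execution window of step s of each completed Go trial — the interval from
#' the previous marker (cue for step 1) to the step's own marker — where it
#' is `sqrt(1 + erds_s/100)`, matching the analysis segmentation so the
#' programmed ERD/S is exact in expectation.
#'
#' @param schedule the schedule the behavior came from (unused beyond
#'   documentation of intent; the behavior carries all timing).
#' @param behavior output of [simulate_behavior()].
#' @param params a [sim_params()].
#' @return list `stream` (a `signal_stream`), `markers` (a
#'   `marker_stream`), and `snr` — the realized ratio of theta RMS to
#'   4-8 Hz band-limited noise RMS.
#' @export
simulate_eeg <- function(schedule, behavior, params) {
  markers <- behavior_markers(behavior)
  fs <- params$eeg_fs_hz
  t_end <- attr(behavior, "t_end_s") + 1.0
  n <- ceiling(t_end * fs)
  tt <- (seq_len(n) - 1L) / fs
  amp <- rep(1, n)
  for (b in seq_along(behavior)) {
    for (r in behavior[[b]]) {
      if (!isTRUE(r$trial$is_go) || r$too_early) next
      bounds <- c(r$cue_time_s, r$responses$timestamp_s)
      for (s in seq_len(length(bounds) - 1L)) {
        i0 <- floor(bounds[s] * fs) + 1L
        i1 <- floor(bounds[s + 1L] * fs)
        if (i1 >= i0) {
          amp[i0:i1] <- sqrt(1 + params$erds_per_step_pct[s] / 100)
        }
      }
    }
  }
  labels <- eeg_channel_labels(params$n_channels)
  x <- matrix(0, params$n_channels, n)
  noise_band_rms <- 0
  with_seed(params$seed + 104729L, {
    phis <- stats::runif(params$n_channels, 0, 2 * pi)
    for (ch in seq_len(params$n_channels)) {
      osc <- amp * params$baseline_theta_amp_uv *
        sin(2 * pi * params$theta_freq_hz * tt + phis[ch])
      nz <- pink_noise(n, fs, params$pink_noise_sd_uv)
      x[ch, ] <- osc + nz
    }
    # realized in-band SNR, from one fresh noise draw
    nz <- pink_noise(n, fs, params$pink_noise_sd_uv)
    if (any(nz != 0)) {
      bp <- signal::butter(4, c(4, 8) / (fs / 2), type = "pass")
      noise_band_rms <- stats::sd(signal::filtfilt(bp, nz))
    }
  })
  theta_rms <- params$baseline_theta_amp_uv / sqrt(2)
  list(stream = signal_stream("eeg", labels, fs, 0, x),
       markers = markers,
       snr = if (noise_band_rms > 0) theta_rms / noise_band_rms else Inf)
}

# Standard 10-20-style labels for up to 22 channels.
eeg_channel_labels <- function(n) {
  full <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4", "Cz",
            "T7", "T8", "P3", "P4", "P7", "P8", "Pz", "O1", "O2", "F9",
            "F10", "POz")
  if (n <= length(full)) full[seq_len(n)] else c(full, sprintf("EX%d", seq_len(n - length(full))))
}

# Cubic smoothstep 3u^2 - 2u^3 on [0, 1].
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate the center-of-mass displacement stream
#'
#' Each response adds an out-and-back excursion centred on its timestamp:
#' displacement ramps to the step's `(dx, dy, dz)` over one smoothstep leg
#' ending at the marker and returns to centre over a second leg. Leg
#' duration is `min(com_ramp_s, interval to the neighbouring step)`, so the
#' peak per-axis speed of an isolated step is `1.5 * |d| / com_ramp_s`.
#'
#' @param behavior output of [simulate_behavior()].
#' @param params a [sim_params()].
#' @return a 3-channel (`x`, `y`, `z`) `signal_stream` at `kin_fs_hz`.
#' @export
simulate_com <- function(behavior, params) {
  fs <- params$kin_fs_hz
  t_end <- attr(behavior, "t_end_s") + 1.0
  n <- ceiling(t_end * fs)
  tt <- (seq_len(n) - 1L) / fs
  x <- matrix(0, 3L, n)
  for (b in seq_along(behavior)) {
    for (r in behavior[[b]]) {
      if (!isTRUE(r$trial$is_go) || r$too_early || !nrow(r$responses)) next
      ts <- r$responses$timestamp_s
      gaps <- diff(ts)
      for (k in seq_along(ts)) {
        Tleg <- min(params$com_ramp_s,
                    if (k > 1L) gaps[k - 1L] else Inf,
                    if (k < length(ts)) gaps[k] else Inf)
        d <- params$com_step_displacement_m[[toupper(r$responses$direction[k])]]
        prof <- numeric(n)
        out_sel <- tt >= ts[k] - Tleg & tt < ts[k]
        prof[out_sel] <- smoothstep((tt[out_sel] - (ts[k] - Tleg)) / Tleg)
        back_sel <- tt >= ts[k] & tt < ts[k] + Tleg
        prof[back_sel] <- 1 - smoothstep((tt[back_sel] - ts[k]) / Tleg)
        x <- x + outer(d, prof)
      }
    }
  }
  signal_stream("com", c("x", "y", "z"), fs, 0, x)
}

#' Simulate one complete synthetic session
#'
#' Runs [simulate_behavior()], [simulate_eeg()] and [simulate_com()] on a
#' schedule and bundles the streams, markers and the ground truth.
#'
#' @param schedule a `session_schedule`.
#' @param params a [sim_params()].
#' @return a `synthetic_session`: list with `schedule`, `behavior`, `eeg`,
#'   `kinematics`, `markers`, `truth` (the params) and `snr`.
#' @export
simulate_session <- function(schedule, params = sim_params()) {
  behavior <- simulate_behavior(schedule, params)
  eeg <- simulate_eeg(schedule, behavior, params)
  com <- simulate_com(behavior, params)
  structure(list(schedule = schedule, behavior = behavior,
                 eeg = eeg$stream, kinematics = com,
                 markers = eeg$markers, truth = params, snr = eeg$snr),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d blocks, EEG %d ch @ %g Hz (%.1f s), SNR %.2f\n",
              length(x$behavior), nrow(x$eeg$samples), x$eeg$fs_hz,
              ncol(x$eeg$samples) / x$eeg$fs_hz, x$snr))
  invisible(x)
}

#' Fit the exponential RT learning curve to simulated (or real) trial means
#'
#' Nonlinear least squares for `rt = asymptote + gain * exp(-decay * trial)`
#' over per-trial mean step RTs of accurate Go trials; used for
#' parameter-recovery checks against the simulator's generative curve.
#'
#' @param behavior output of [simulate_behavior()] (training blocks are
#'   used), or a data.frame with columns `trial` (0-based Go counter) and
#'   `rt_ms`.
#' @return list `asymptote_ms`, `gain_ms`, `decay_per_trial`, `n_trials`.
#' @export
fit_rt_curve <- function(behavior) {
  if (is.data.frame(behavior)) {
    df <- behavior
  } else {
    rows <- list()
    go_counter <- -1L
    for (b in seq_along(behavior)) {
      for (r in behavior[[b]]) {
        if (!isTRUE(r$trial$is_go)) next
        go_counter <- go_counter + 1L
        if (r$too_early || !all(r$per_step_correct)) next
        rows[[length(rows) + 1L]] <- data.frame(trial = go_counter,
                                                rt_ms = mean(r$step_rts_ms))
      }
    }
    df <- do.call(rbind, rows)
  }
  fit <- stats::nls(rt_ms ~ a + g * exp(-d * trial), data = df,
                    start = list(a = min(df$rt_ms), g = diff(range(df$rt_ms)) + 1,
                                 d = 0.05),
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  co <- stats::coef(fit)
  list(asymptote_ms = unname(co["a"]), gain_ms = unname(co["g"]),
       decay_per_trial = unname(co["d"]), n_trials = nrow(df))
}
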