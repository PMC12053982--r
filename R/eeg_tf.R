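# Theta ERD/S pipeline: band-pass and average-reference preprocessing, a
# pluggable artifact-removal hook, complex Morlet wavelet theta power,
# fixed-bin time normalization of variable-length epochs, and the ERD/S
# percentage relative to the 200 ms pre-cue baseline:
#
#   ERD/S(%) = (P_timepoint - P_baseline) / P_baseline * 100
#
# Negative values are event-related desynchronization (power drop), positive
# values synchronization.

#' Zero-phase band-pass filter
#'
#' Cascaded zero-phase Butterworth filtering (order-2 high-pass + order-4
#' low-pass, each applied forward-backward with [signal::filtfilt()]), giving
#' flat passband gain, DC rejection and no phase distortion. Default corners
#' 0.3-30 Hz.
#'
#' @param stream a `signal_stream`.
#' @param low_hz,high_hz corner frequencies; requires `fs > 2*high_hz`.
#' @return the filtered stream, shape preserved.
#' @export
bandpass <- function(stream, low_hz = 0.3, high_hz = 30) {
  fs <- stream$fs_hz
  if (fs <= 2 * high_hz) {
    stop_invalid("sampling rate %g Hz too low for a %g Hz upper corner", fs, high_hz)
  }
  if (low_hz <= 0 || low_hz >= high_hz) stop_invalid("need 0 < low_hz < high_hz")
  hp <- signal::butter(2, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(4, high_hz / (fs / 2), type = "low")
  x <- stream$samples
  for (ch in seq_len(nrow(x))) {
    y <- signal::filtfilt(hp, x[ch, ])
    x[ch, ] <- signal::filtfilt(lp, y)
  }
  stream$samples <- x
  stream
}

#' Re-reference to the common average
#'
#' Subtracts the cross-channel mean at every sample, so channel sums are zero
#' everywhere (a computed average reference electrode).
#'
#' @param stream a `signal_stream` with at least two channels.
#' @return the re-referenced stream.
#' @export
average_reference <- function(stream) {
  if (nrow(stream$samples) < 2L) {
    stop_invalid("average reference needs at least 2 channels")
  }
  stream$samples <- sweep(stream$samples, 2L, colMeans(stream$samples))
  stream
}

#' Pluggable artifact-removal hook
#'
#' Artifact removal (e.g. ICA-based component rejection) is delegated, not
#' implemented here: `method = "none"` is the identity, a function is called
#' as `method(stream, ...)`. The applied method name is recorded in the
#' stream's `artifact_log` attribute.
#'
#' @param stream a `signal_stream`.
#' @param method `"none"` or a function `stream -> stream`.
#' @param ... passed on to a function method.
#' @return the (possibly) cleaned stream.
#' @export
artifact_removal_hook <- function(stream, method = "none", ...) {
  log_entry <- list(method = if (is.function(method)) "injected" else method,
                    params = list(...))
  if (is.function(method)) {
    stream <- method(stream, ...)
  } else if (identical(method, "none")) {
    # identity
  } else {
    stop_invalid("unknown artifact-removal method '%s'", method)
  }
  attr(stream, "artifact_log") <- c(attr(stream, "artifact_log"), list(log_entry))
  stream
}

# Complex Morlet transform of one channel at one frequency, FFT convolution.
# Edge handling: the epoch is extended at both ends over the wavelet's half
# support before convolving — with real recording context where available,
# mirror reflection otherwise. A hard zero edge has broadband energy that
# detuned wavelets in the band pick up; a smooth extension suppresses that
# leakage so both oscillation and noise keep near-flat band power into the
# trimmed region (and real context removes the edge bias entirely).
morlet_conv_power <- function(x, fs, freq, n_cycles,
                              pre = numeric(0), post = numeric(0)) {
  n <- length(x)
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sigma_t * fs)
  take_pre <- min(half, length(pre))
  take_post <- min(half, length(post))
  left <- if (take_pre) pre[seq.int(length(pre) - take_pre + 1L, length(pre))] else numeric(0)
  right <- if (take_post) post[seq_len(take_post)] else numeric(0)
  need_l <- half - take_pre
  need_r <- half - take_post
  core <- c(left, x, right)
  if (need_l > 0L) {
    ext <- min(need_l, length(core) - 1L)
    core <- c(core[seq(ext + 1L, 2L)], core)
    take_pre <- take_pre + ext
  }
  if (need_r > 0L) {
    nc <- length(core)
    ext <- min(need_r, nc - 1L)
    core <- c(core, core[seq(nc - 1L, nc - ext)])
  }
  xx <- core
  m <- length(xx)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(2i * pi * freq * t)
  w <- w / sum(env)                      # unit response to a matched sinusoid
  nw <- length(w)
  nfft <- stats::nextn(m + nw - 1L, 2L)
  X <- stats::fft(c(xx, rep(0, nfft - m)))
  W <- stats::fft(c(w, rep(0, nfft - nw)))
  conv <- stats::fft(X * W, inverse = TRUE) / nfft
  conv <- conv[half + take_pre + seq_len(n)]  # centre-aligned, extension dropped
  Mod(conv)^2
}

#' Morlet wavelet theta band power of an epoch
#'
#' Convolves every channel with complex Morlet wavelets at `freqs_hz`
#' (default 4-8 Hz in 1 Hz steps, 5 cycles), averages power across the band,
#' then trims the epoch's padding interval so wavelet edge effects fall
#' outside the retained series.
#'
#' @param ep an [epoch()] (must include its padding).
#' @param freqs_hz wavelet centre frequencies (Hz).
#' @param n_cycles wavelet cycles (sets time-frequency trade-off;
#'   `sigma_t = n_cycles / (2 pi f)`).
#' @return a `theta_power` object: `times_s` (relative to the cue), `power`
#'   (channels x time, band-average power, signal-units squared),
#'   `channel_labels`, plus the epoch's cue/step geometry.
#' @export
morlet_theta_power <- function(ep, freqs_hz = 4:8, n_cycles = 5) {
  n <- ncol(ep$data)
  fs <- ep$fs_hz
  sigma_max <- n_cycles / (2 * pi * min(freqs_hz))
  if (n / fs < 2 * sigma_max) {
    stop_invalid("epoch too short (%.3f s) for a %g-cycle wavelet at %g Hz",
                 n / fs, n_cycles, min(freqs_hz))
  }
  pow <- matrix(0, nrow(ep$data), n)
  for (ch in seq_len(nrow(ep$data))) {
    pre <- if (!is.null(ep$context_pre)) ep$context_pre[ch, ] else numeric(0)
    post <- if (!is.null(ep$context_post)) ep$context_post[ch, ] else numeric(0)
    p <- 0
    for (f in freqs_hz) {
      p <- p + morlet_conv_power(ep$data[ch, ], fs, f, n_cycles, pre, post)
    }
    pow[ch, ] <- p / length(freqs_hz)
  }
  times_rel <- (seq_len(n) - 1L) / fs - ep$cue_offset_s   # relative to cue
  pad_n <- round(ep$pad_s * fs)
  keep <- seq.int(pad_n + 1L, n - pad_n)
  structure(list(times_s = times_rel[keep],
                 power = pow[, keep, drop = FALSE],
                 channel_labels = ep$channel_labels,
                 step_offsets_s = ep$step_offsets_s,
                 baseline_window_s = ep$baseline_window_s,
                 fs_hz = fs, trial_index = ep$trial_index, block = ep$block,
                 anchor = if (!is.null(ep$anchor)) ep$anchor else "cue"),
            class = "theta_power")
}

#' Baseline band power
#'
#' Mean band power per channel over the pre-cue baseline window
#' (default -200 to 0 ms relative to the cue).
#'
#' @param tp a `theta_power` from [morlet_theta_power()].
#' @param window_s window relative to the cue, default the epoch's own.
#' @return numeric vector, one positive value per channel.
#' @export
baseline_power <- function(tp, window_s = tp$baseline_window_s) {
  sel <- tp$times_s >= window_s[1] & tp$times_s < window_s[2]
  if (!any(sel)) stop_invalid("baseline window [%g, %g) contains no samples",
                              window_s[1], window_s[2])
  rowMeans(tp$power[, sel, drop = FALSE])
}

# 0-based bin index of 1-based sample j among N samples and B bins,
# equivalent to the explicit index windows [floor(N*b/B), floor(N*(b+1)/B)).
bin_index <- function(N, B) as.integer(ceiling(seq_len(N) * B / N)) - 1L

# Reduce one numeric vector to B bin means by equally spaced index windows.
bin_means <- function(x, B) {
  N <- length(x)
  if (N == 0L) return(rep(NA_real_, B))
  idx <- bin_index(N, B)
  means <- rep(NA_real_, B)
  agg <- tapply(x, idx, mean)
  means[as.integer(names(agg)) + 1L] <- agg
  if (anyNA(means)) {      # more bins than samples: fill from nearest sample
    centers <- (seq_len(B) - 0.5) * N / B
    empty <- which(is.na(means))
    means[empty] <- x[pmin(pmax(round(centers[empty] + 0.5), 1L), N)]
    warning(sprintf("%d bin(s) had no samples; filled by nearest-sample value",
                    length(empty)), call. = FALSE)
  }
  means
}

# Bin means applied row-wise; always returns nrow x B.
row_bin_means <- function(m, B) {
  out <- matrix(NA_real_, nrow(m), B)
  for (ch in seq_len(nrow(m))) out[ch, ] <- bin_means(m[ch, ], B)
  out
}

#' Fixed-bin time normalization of a variable-length power series
#'
#' Reduces the execution span of an epoch to exactly `n_bins` datapoints so
#' epochs of different durations are comparable. `mode = "per_step"`
#' (default) splits the span into the six cue/step segments (cue->s1,
#' s1->s2, ..., s5->s6) and gives each segment `n_bins/6` equally spaced bin
#' means, keeping bins aligned to step boundaries; `mode = "global"` places
#' `n_bins` equally spaced bins across the whole span regardless of step
#' structure.
#'
#' @param tp a `theta_power`, or a plain numeric vector/matrix of samples
#'   spanning exactly the execution window (then `cue_offset`/`step_offsets`
#'   are ignored in global mode).
#' @param n_bins total output bins (default 300; must be divisible by the
#'   number of segments in per-step mode).
#' @param mode `"per_step"` or `"global"`.
#' @return matrix channels x `n_bins` (or a vector for vector input).
#' @export
time_normalize <- function(tp, n_bins = 300, mode = c("per_step", "global")) {
  mode <- match.arg(mode)
  plain <- !inherits(tp, "theta_power")
  if (plain) {
    x <- if (is.matrix(tp)) tp else matrix(tp, nrow = 1L)
    if (mode != "global") stop_invalid("per-step mode needs a theta_power with step offsets")
    out <- row_bin_means(x, n_bins)
    return(if (is.matrix(tp)) out else drop(out))
  }
  x <- tp$power
  t_rel <- tp$times_s
  bounds <- if (identical(tp$anchor, "first_step")) tp$step_offsets_s else
    c(0, tp$step_offsets_s)
  n_seg <- length(bounds) - 1L
  span <- t_rel >= bounds[1] & t_rel < bounds[length(bounds)]
  if (mode == "global") {
    return(row_bin_means(x[, span, drop = FALSE], n_bins))
  }
  if (n_bins %% n_seg != 0L) {
    stop_invalid("n_bins = %d not divisible by %d segments", n_bins, n_seg)
  }
  per <- n_bins %/% n_seg
  out <- matrix(NA_real_, nrow(x), 0L)
  for (s in seq_len(n_seg)) {
    sel <- t_rel >= bounds[s] & t_rel < bounds[s + 1L]
    if (!any(sel)) {
      # degenerate segment between two near-coincident markers: fall back to
      # the sample nearest the segment centre
      ctr <- (bounds[s] + bounds[s + 1L]) / 2
      j <- which.min(abs(t_rel - ctr))
      seg <- matrix(rep(x[, j], per), nrow(x), per)
      warning(sprintf("segment %d shorter than one sample; bins filled by nearest sample", s),
              call. = FALSE)
    } else {
      seg <- row_bin_means(x[, sel, drop = FALSE], per)
    }
    out <- cbind(out, seg)
  }
  rownames(out) <- tp$channel_labels
  out
}

#' Collapse 300 normalized datapoints into six per-step estimates
#'
#' Six means of consecutive groups of `length/6` values — with the default
#' 300 bins, six groups of 50 — giving one theta power estimate per step.
#'
#' @param norm300 vector of length 300 (or a channels x 300 matrix), as from
#'   [time_normalize()]. Length must be divisible by 6.
#' @return vector of 6 means (or channels x 6 matrix).
#' @export
step_bins <- function(norm300) {
  x <- if (is.matrix(norm300)) norm300 else matrix(norm300, nrow = 1L)
  B <- ncol(x)
  if (B %% 6L != 0L) stop_invalid("length %d is not divisible into 6 step bins", B)
  g <- rep(seq_len(6L), each = B %/% 6L)
  out <- t(apply(x, 1L, function(r) tapply(r, g, mean)))
  if (is.matrix(norm300)) out else drop(out)
}

#' ERD/S percentage
#'
#' `(P_timepoint - P_baseline) / P_baseline * 100`; scale-invariant in the
#' two powers.
#'
#' @param power_timepoint theta power at the timepoint/step (vectorized).
#' @param power_baseline baseline theta power, must be positive.
#' @return ERD/S in percent (negative = desynchronization).
#' @export
erds_percent <- function(power_timepoint, power_baseline) {
  if (any(power_baseline <= 0)) stop_invalid("baseline power must be > 0")
  (power_timepoint - power_baseline) / power_baseline * 100
}

#' Per-step theta ERD/S profile of one epoch
#'
#' Full per-epoch chain: Morlet theta power, padding trim, fixed-bin time
#' normalization, six step bins, and ERD/S against the epoch's own pre-cue
#' baseline — per channel.
#'
#' @param ep an [epoch()].
#' @param freqs_hz,n_cycles wavelet parameters, see [morlet_theta_power()].
#' @param n_bins,mode normalization parameters, see [time_normalize()].
#' @return data.frame keyed (trial_index, block, channel, step) with
#'   `erds_pct`.
#' @export
erds_profile <- function(ep, freqs_hz = 4:8, n_cycles = 5, n_bins = 300,
                         mode = "per_step") {
  tp <- morlet_theta_power(ep, freqs_hz = freqs_hz, n_cycles = n_cycles)
  base <- baseline_power(tp)
  norm <- time_normalize(tp, n_bins = n_bins, mode = mode)
  per_step <- step_bins(norm)                     # channels x 6
  n_ch <- nrow(per_step)
  data.frame(
    trial_index = ep$trial_index,
    block = ep$block,
    channel = rep(tp$channel_labels, each = 6L),
    step = rep(seq_len(6L), times = n_ch),
    erds_pct = as.vector(t(erds_percent(per_step, base)))
  )
}

#' Average per-step ERD/S over many epochs
#'
#' Two orders of averaging are offered. `average = "power"` (default, the
#' classical ERD/S convention) averages the per-step and baseline theta
#' powers across epochs first and takes the ratio once per
#' (block, channel, step): with a short baseline window the per-epoch ratio
#' is a noisy-denominator estimator whose expectation is biased upward, and
#' pooling the denominator across epochs removes that bias.
#' `average = "ratio"` computes [erds_profile()] per epoch and averages the
#' per-epoch percentages.
#'
#' @param epochs list of [epoch()]s.
#' @param participant participant id column value.
#' @param average `"power"` (pool powers across epochs, then ratio) or
#'   `"ratio"` (per-epoch ERD/S, then mean).
#' @param freqs_hz,n_cycles,n_bins,mode passed to the per-epoch stages.
#' @return tidy data.frame keyed (participant, block, channel, step) with
#'   `erds_pct` and `n_epochs`.
#' @export
erds_table <- function(epochs, participant = 1L,
                       average = c("power", "ratio"),
                       freqs_hz = 4:8, n_cycles = 5, n_bins = 300,
                       mode = "per_step") {
  average <- match.arg(average)
  if (average == "ratio") {
    profs <- do.call(rbind, lapply(epochs, erds_profile, freqs_hz = freqs_hz,
                                   n_cycles = n_cycles, n_bins = n_bins,
                                   mode = mode))
    profs$block[is.na(profs$block)] <- 0L
    agg <- stats::aggregate(erds_pct ~ block + channel + step, data = profs, FUN = mean)
    n <- stats::aggregate(erds_pct ~ block + channel + step, data = profs, FUN = length)
    agg$n_epochs <- n$erds_pct
    return(cbind(participant = participant,
                 agg[order(agg$block, agg$channel, agg$step), ]))
  }
  rows <- lapply(epochs, function(ep) {
    tp <- morlet_theta_power(ep, freqs_hz = freqs_hz, n_cycles = n_cycles)
    base <- baseline_power(tp)
    per_step <- step_bins(time_normalize(tp, n_bins = n_bins, mode = mode))
    n_ch <- length(tp$channel_labels)
    data.frame(block = if (is.na(ep$block)) 0L else ep$block,
               channel = rep(tp$channel_labels, each = 6L),
               step = rep(seq_len(6L), times = n_ch),
               step_power = as.vector(t(per_step)),
               base_power = rep(base, each = 6L))
  })
  pooled <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(step_power, base_power) ~ block + channel + step,
                          data = pooled, FUN = mean)
  n <- stats::aggregate(step_power ~ block + channel + step, data = pooled,
                        FUN = length)
  agg$erds_pct <- erds_percent(agg$step_power, agg$base_power)
  agg$n_epochs <- n$step_power
  out <- agg[order(agg$block, agg$channel, agg$step),
             c("block", "channel", "step", "erds_pct", "n_epochs")]
  cbind(participant = participant, out)
}
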