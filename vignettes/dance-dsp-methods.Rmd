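---
title: "Methods: task generation, synthetic sessions and per-step theta ERD/S"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task generation, synthetic sessions and per-step theta ERD/S}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dancedsp)
```

## The task and what the package computes

`dancedsp` supports whole-body motor sequence learning experiments built on
the discrete sequence production (DSP) paradigm transferred to a
four-direction dance mat. A trial presents a six-step direction sequence
(placeholders lighting up for 750 ms each after a 1000 ms fixation), then a
1500 ms blank, then a Go or NoGo cue. On Go the participant reproduces the
sequence by stepping on the mat; on NoGo they stand still for three seconds.
This cue structure separates sequence preparation from execution. The
package provides, as composable stages:

1. **Task engine** — sequence rotation counterbalancing, Go/NoGo block and
   session scheduling with the standard break structure, trial timelines,
   and response scoring.
2. **Simulator** — complete synthetic multimodal sessions (behavior, EEG,
   center-of-mass kinematics, markers) with known ground truth.
3. **Multistream synchronization and epoching** — constant-offset clock
   alignment and variable-length, marker-defined epochs.
4. **Theta ERD/S analysis** — Morlet wavelet theta power, fixed-bin time
   normalization, per-step event-related desynchronization/synchronization.
5. **Kinematics** — per-axis center-of-mass velocity and per-step /
   per-sequence / per-block summaries.

## Counterbalancing by rotation

Directions rotate clockwise a quarter turn at a time
(`LEFT -> UP -> RIGHT -> DOWN -> LEFT`). Rotating both base sequences
through all four turns yields eight positionally distinct but structurally
identical sequences; participant *i* practices the pair at rotation
`i mod 4`, and the test phase presents a familiar and a novel block in an
order set by participant parity. Degenerate inputs (a pair whose rotations
collide) are rejected with an error naming the colliding set members.

```{r rotation}
rotate_sequence(dance_sequence("LRUDRL"), 1)
```

A default block schedules 24 Go trials per sequence plus 4 NoGo trials
(92 % / 8 %) in a single seeded shuffle; NoGo trials alternate which
sequence they display, and no adjacency constraint is imposed — the seeded
shuffle is the entire ordering model. A default session (4 training + 2
test blocks) therefore schedules `6 * 48 * 6 = 1728` Go steps. The 4 NoGo
trials are additive (52 trials per block), the reading we apply of "48
trials with 4 NoGo trials"; the config documents this.

Step-level response time is the latency of step 1 from the Go cue plus
inter-step intervals for steps 2–6, the standard DSP convention. Trials
with any response before the Go cue (or any response on NoGo) are marked
too-early, excluded, and not re-queued.

## The synthetic-session generator

The generator is first-class, tested code: its defaults define the study
conditions that the acceptance checks run under, and they were fixed once,
up front.

* **Behavior.** Step RTs follow
  `RT(t) = asymptote + gain * exp(-decay * t) + N(0, sd)` over the
  cumulative Go-trial counter `t`, truncated at 50 ms. Defaults
  `asymptote = 300` ms, `gain = 227` ms, `decay = 0.02` per trial were
  calibrated so the expected mean step RT over a 192-trial learning phase
  is ~358 ms, matching the magnitude reported for this task class, with
  learning essentially plateaued by the fourth block. `sd = 50` ms;
  each step is independently wrong with probability 0.05. The simulated
  timeline runs trials back to back with a 1 s feedback interval; rest
  breaks stay in the schedule metadata and are not materialized as signal,
  which keeps stream sizes proportional to trial count.
* **EEG.** Each of 22 channels (standard 10–20-style labels, 500 Hz)
  carries a 6 Hz, 10 uV sinusoid with a random channel phase. During the
  execution window of step *s* (previous marker to the step's own marker,
  matching the analysis segmentation) the amplitude is scaled by
  `sqrt(1 + ERDS_s / 100)` — power-correct, so the programmed per-step
  ERD/S is exact in expectation. The default truth spans both
  desynchronization and synchronization: `c(-40, -25, -10, 5, 20, 35)` %.
  Independent seeded 1/f noise (total SD 7 uV) yields a realized in-band
  (4–8 Hz) amplitude SNR near 3, reported in the manifest.
* **Kinematics.** The center-of-mass trace (100 Hz) sums cubic smoothstep
  out-and-back excursions centred on each response: one leg ramps to the
  step's `(dx, dy, dz)` displacement (0.3 m on the step's axis, 0.02 m
  vertical) ending at the marker, a second leg returns to centre. Leg
  duration is `min(0.4 s, neighbouring inter-step interval)`, so an
  isolated step peaks at `1.5 * |d| / 0.4` m/s per axis.

What the generator does **not** emulate: volume conduction or any forward
head model, movement or ocular artifacts beyond broadband 1/f noise,
non-sinusoidal or frequency-drifting theta, biomechanically realistic gait,
clock drift between devices, or too-early responses. Passing recovery tests
therefore demonstrates that the pipeline's arithmetic is correct and
unbiased under its own signal model — not that it is robust to real-world
artifacts, which is what the pluggable artifact-removal hook is for.

## Epochs

Epochs are anchored at the Go cue: span
`[cue - 0.2 s - pad, last step + pad]` with `pad = 0.1` s, cut by
nearest-sample rounding, with half-open sample windows throughout. The cue
anchor (rather than the first step) gives exactly six per-step segments
(cue->s1, s1->s2, ..., s5->s6) and keeps the 200 ms pre-cue baseline inside
every epoch; `anchor = "first_step"` is available for the five-segment
reading. Trials missing step markers are skipped with a logged reason. Epoch
durations track execution speed (roughly 0.5–6 s, i.e. ~250–3000 samples at
500 Hz).

Each epoch also carries up to 0.5 s of surrounding raw recording
(`context_pre` / `context_post`). This is not part of the epoch span; it is
used purely as convolution context by the wavelet stage (below). Clock
alignment is a constant offset per stream; drift correction is out of scope
for file-based analysis of synchronized recordings.

## Theta ERD/S

Preprocessing: cascaded zero-phase Butterworth filtering (order-2 high-pass
at 0.3 Hz plus order-4 low-pass at 30 Hz, each forward–backward) — a single
narrow band-pass at a 0.0012 normalized corner is numerically fragile, and
the cascade's passband/stopband behaviour is asserted in tests. Then a
computed average reference, then the artifact hook (`"none"` by default; an
ICA-based cleaner can be injected).

Per epoch and channel, complex Morlet wavelets at 4–8 Hz (1 Hz spacing, 5
cycles; both exposed in the config) give band-average power; the 100 ms
padding is trimmed; the execution span is reduced to 300 bins; consecutive
groups of 50 bins give one theta estimate per step; and

```
ERD/S(%) = (P_step - P_baseline) / P_baseline * 100
```

with the baseline the mean band power over [-200, 0) ms before the cue.

Numerical choices worth recording:

* **Edge handling.** A truncated epoch has a hard edge whose broadband
  energy detuned wavelets pick up, and naive corrections amplify it: we
  measured zero-padding with Gaussian-mass renormalization inflating
  baseline-region band power by ~13 %, and a C1 point-symmetric extension
  fixing sinusoids but roughly doubling noise variance at the edges. The
  shipped design convolves over the epoch's real recording context when
  present and falls back to mirror reflection (variance-preserving, ~3 %
  residual phase-averaged bias) for bare epochs.
* **Binning.** `n_bins = 300` bins are equally spaced index windows:
  0-based bin `b` of an `N`-sample segment averages samples
  `floor(N*b/B) .. floor(N*(b+1)/B) - 1` (equivalently, a sample's midpoint
  assigns it to a bin, ties to the upper bin — the convention that makes
  the windows exact). Per-step mode (default) gives each of the six
  cue/step segments 50 bins, retaining step alignment; global mode places
  300 bins across the whole span, the literal equally-spaced reading. A
  segment shorter than one sample is filled from the nearest sample with a
  warning.
* **Order of averaging.** `erds_table()` defaults to pooling step and
  baseline powers across epochs before taking the ratio. The per-epoch
  ratio uses a denominator estimated from ~0.2 s of data (a handful of
  independent samples at theta); its expectation is biased upward, and we
  measured +5 to +20 percentage points of spurious synchronization per
  session at SNR 3. Pooling the denominator across 20+ epochs removes
  this. `average = "ratio"` provides the per-epoch-first alternative.
* **Known residual bias.** The wavelet's temporal support
  (`sigma_t = 0.08–0.2` s across the band at 5 cycles) straddles the cue:
  the baseline window sits next to the step-1 execution window, so strong
  step-1 ERD bleeds into the baseline and shifts all steps up by a few
  points; SNR-3 noise attenuates the ratio toward zero. At the validation
  scale below the combined mean absolute recovery error is ~7–9 points.

## Kinematics

Velocity and acceleration use central differences (one-sided at the ends),
second-order accurate on smooth traces — the estimator is a package choice,
as inertial-suite exports do not prescribe one. Per-step windows are the
same half-open cue/step segments as the EEG analysis, so they tile the
execution span exactly. Both signed mean velocity and mean absolute
velocity are exported per axis (summary statistics in the field vary on
this point); block summaries default to accurate Go trials only, mirroring
the behavioral analysis. The axis convention is the simulator's
(x left–right, y forward–back, z vertical); real motion-capture exports can
be remapped via the config.

## Validation scales and determinism

The test suite validates, among unit-level properties:

* global binning against an explicit index-window brute force on 200 random
  epoch lengths in [300, 3000];
* end-to-end ERD/S recovery on a seeded 2-block synthetic session
  (96 epochs, 22 channels, SNR ~ 3) with mean absolute error within 10
  percentage points of the programmed truth;
* exponential RT-curve recovery within 20 % from 192 simulated trials;
* kinematic peak-velocity recovery within 2 % of the smoothstep closed
  form;
* bit-identical reruns: one seed drives scheduling, behavior, noise and
  channel phases, so identical seeds give identical sessions, tables and
  output hashes end to end.

These problem sizes (one to two blocks, 2–22 channels) were chosen so the
whole suite exercises every stage at the scale the method is meant for
while remaining comfortable to run routinely.

## Limitations

Real XDF containers are not parsed — recordings travel as the CSV bundle
(one CSV per stream, a marker CSV, and JSON metadata) written and read by
the package; EDF ingest is likewise out of scope in this build. ICA is
deliberately not implemented (hook only). The linear mixed-effects modelling
of learning curves and any between-participant statistics are left to
standard tools on the exported tidy tables.
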