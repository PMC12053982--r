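# dancedsp

Tools for whole-body motor sequence learning experiments that transfer the
discrete sequence production (DSP) paradigm from a keyboard to a
four-direction dance mat, recorded with mobile EEG and inertial motion
capture. The package is aimed at motor-learning and mobile brain/body
imaging researchers who need (a) reproducible task schedules, (b) a
synthetic multimodal session generator with known ground truth to validate
their analysis chain, and (c) the analysis chain itself: marker-synchronized
epoching, per-step theta ERD/S, and center-of-mass kinematics.

## What it computes

**Task engine.** Six-step direction sequences over {UP, DOWN, LEFT, RIGHT}
are counterbalanced by clockwise quarter-turn rotation
(`LEFT -> UP -> RIGHT -> DOWN -> LEFT`): two base sequences rotated four
times give eight positionally distinct, structurally identical sequences.
Blocks schedule 24 Go trials per sequence plus 4 NoGo trials (92 % / 8 %)
in a single seeded shuffle; a default session (4 training + 2 test blocks)
schedules 6 x 48 x 6 = 1728 steps. Responses are scored step by step
("Good", "Too early!", or the 1-based wrong-step positions), with
step-level RT = cue latency for step 1 plus inter-step intervals.

**Theta ERD/S.** For each Go-trial epoch (cue - 0.2 s - pad to last step +
pad, pad = 100 ms), band-average power from complex Morlet wavelets at
4–8 Hz is time-normalized to 300 bins (aligned to the six cue/step
segments, 50 bins each), collapsed to one estimate per step, and expressed
relative to the 200 ms pre-cue baseline:

    ERD/S(%) = (P_step - P_baseline) / P_baseline * 100

negative = event-related desynchronization, positive = synchronization.

**Kinematics.** Center-of-mass displacement (100 Hz) is differentiated by
central differences into per-axis velocity/acceleration and summarized over
the same per-step windows, per sequence and per block.

**Simulator.** `simulate_session()` generates behavior from an exponential
RT learning curve, EEG whose theta amplitude is scaled power-correctly by
`sqrt(1 + ERDS/100)` inside each step's execution window plus seeded 1/f
noise, a smoothstep CoM trace, and the shared marker stream — all from one
seed, bit-reproducibly. Recovery of the programmed parameters through the
full pipeline is the package's principal validation.

## Worked example

```r
library(dancedsp)

cb   <- build_counterbalance_set("LRUDRL", "RULURD")  # 8 sequences
pair <- assign_participant_pair(cb, 0)
blk  <- schedule_block(pair, n_go_per_seq = 12, n_nogo = 2, seed = 7)
sess <- structure(list(blocks = list(blk)), class = "session_schedule")

syn <- simulate_session(sess, sim_params(n_channels = 4, seed = 7))
#> <synthetic_session> 1 blocks, EEG 4 ch @ 500 Hz (284.8 s), SNR 3.38

eeg <- average_reference(bandpass(syn$eeg))
eps <- extract_sequence_epochs(eeg, syn$markers)   # 24 epochs
tab <- erds_table(eps)                             # (participant, block, channel, step)
aggregate(erds_pct ~ step, tab, mean)
#>  step recovered programmed
#>     1     -28.1        -40
#>     2     -22.5        -25
#>     3      -7.1        -10
#>     4       9.5          5
#>     5      23.2         20
#>     6      30.9         35
```

The recovered per-step theta ERD/S tracks the simulator's programmed
profile (mean absolute error 4.9 percentage points here, from 24 epochs at
in-band SNR 3.4); desynchronization during early steps and synchronization
during late steps are both resolved. Residual deviations are the wavelet's
temporal smearing across the cue boundary and noise attenuation of the
power ratio — see the methods vignette (`vignettes/dance-dsp-methods.Rmd`).
`kinematics_table()` and `block_summary()` produce the matching per-step
CoM velocity table and the end-of-block behavioral feedback
(mean RT, mistake %). `run_pipeline(config, out_dir)` runs
schedule -> simulate -> preprocess -> epoch -> tables end to end and writes
a manifest with stage counts and output hashes;
`scripts/dance_dsp.R <schedule|simulate|erds|kinematics|report>` is the
command-line wrapper.

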