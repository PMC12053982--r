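Package: dancedsp
Title: Dance Discrete Sequence Production Task Scheduling, Simulation and
    Mobile Brain-Body Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-body motor sequence learning experiments built on
    the discrete sequence production (DSP) paradigm transferred to a
    four-direction dance mat. Generates rotation-counterbalanced six-step
    sequences, Go/NoGo block and session schedules with break structure, and
    scores step-level responses. Simulates complete synthetic multimodal
    sessions (behavior with an exponential response-time learning curve,
    multichannel theta-band EEG with programmed per-step event-related
    de/synchronization, center-of-mass kinematics, and an event-marker
    stream) with known ground truth for pipeline validation. Provides
    marker-synchronized multistream alignment, variable-length epoch
    extraction, Morlet wavelet theta power with fixed-bin time normalization
    and per-step ERD/S percentages, and center-of-mass
    displacement/velocity/acceleration summaries per step, sequence and block.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
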