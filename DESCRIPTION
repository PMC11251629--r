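Package: emgsim
Title: Full-Spectrum Surface EMG Simulation During Voluntary Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular simulator for multi-channel surface electromyography
    (EMG) during voluntary hand, wrist and forearm movements. Movements are
    defined as interpolated pose sequences or OpenSim-style .mot motion
    files; muscle fibre lengths are deduced under a rigid-tendon assumption
    and muscle activations estimated by static optimization; fibre-length
    changes are converted to conduction-velocity and motor-unit-depth
    trajectories under a constant-volume assumption; motor unit pools
    (classical Fuglevand recruitment/rate-coding model and a cohort of leaky
    integrate-and-fire motoneurons) transform neural drive into spike
    trains; an analytical line-source volume-conductor model generates motor
    unit action potential (MUAP) templates on a 10 x 32 electrode grid
    conditioned on seven physiological parameters and morphs them along a
    movement; EMG is synthesised as the summation of the convolution of the
    dynamic MUAPs with the spike trains. Includes MUAP similarity analyses
    (normalised mean square error with amplitude-based cropping), windowed
    RMS feature extraction, and an end-to-end synthetic data-augmentation
    demonstration for joint-angle regression with ridge regressors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
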