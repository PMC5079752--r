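Package: pupildyn
Title: Dynamics of the Pupillary Light Response: Dose-Response, Kinetics,
    Feedback Simulation and Contribution Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for mouse pupillometry time series. Converts
    pupil-area traces to relative pupil area, fits constrained variable-slope
    sigmoidal intensity-response curves (EC50 on the log scale), fits one- and
    two-phase exponential kinetics with half-lives, simulates an iterative
    negative-feedback model bounding the pupil's own contribution to response
    decay, builds time-by-intensity pupil matrices per genotype and derives
    necessity/sufficiency/contribution heat maps, and generates synthetic
    genotype-specific pupil traces for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
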