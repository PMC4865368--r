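Package: saccomp
Title: Saccadic Error Comparator Analysis for Trial-Structured Spike Recordings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how posterior parietal cortex computes
    saccadic motor error. Detects primary and corrective (secondary) saccades
    from 1 kHz eye-position traces, estimates Gaussian-kernel spike densities,
    locates firing-rate decay and rise times by exponential-fit change-point
    search, classifies neurons into persistent peri-saccadic (PPS, intended
    end-position) and late post-saccadic (LPS, actual end-position) classes,
    and runs the reference-subtraction comparator analyses that relate
    post-subtraction PPS activity to saccadic error and to the probability of
    a corrective saccade. Includes a fully parameterised synthetic-session
    generator (inhomogeneous-Poisson spike trains plus minimum-jerk eye
    kinematics) with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
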