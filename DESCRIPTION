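Package: nigrastim
Title: Peri-Stimulus Spike-Train Analysis of Substantia Nigra Responses to Motor-Cortex High-Frequency Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how substantia nigra neurons respond to
    high-frequency stimulation (HFS) of the primary motor cortex. Builds
    peri-event time histograms (PETH), rasters and difference curves from
    event-aligned spike trains; computes mean firing rates in the baseline
    (BE), tetanization (TT) and post-event (PE) windows; classifies each
    neuron into the four tetanic/post-tetanic response types (TD-PTD,
    TD-PTP, TP-PTP, TP-PTD); and summarises groups by type proportions and
    magnitude fold-change ratios (M_BE/M_TT, M_BE/M_PE). Includes a
    ground-truth synthetic cohort generator (piecewise-homogeneous Poisson
    spike trains, optional raw voltage traces), an amplitude-discrimination
    spike detector, and the group-level statistical battery (two-proportion
    z-test with exact fallback, Student's t, one-way ANOVA with Tukey HSD,
    Cohen's d, Shapiro-Wilk and Levene checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse,
    yaml
Config/testthat/edition: 3
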