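Package: chronocline
Title: Circadian Rhythmicity, Sleep and Photoperiodic Diapause Analysis for
    Fly Activity-Monitor, Staining and Response-Curve Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse chronobiological experiments on latitudinal
    fly populations: reading and writing Trikinetics-style Drosophila
    Activity Monitor (DAM) beam-count files; sleep scoring by the 5-minute
    immobility rule; average daily activity profiles and morning/evening
    peak-phase estimation from double-plotted, loess-smoothed profiles;
    Lomb-Scargle periodogram rhythmicity classification in constant
    darkness; a JTK-style nonparametric cycling test (Jonckheere-Terpstra
    statistic against phase-lagged cosine references) for immunostaining
    time series; ROI-based confocal image intensity quantification; and
    logistic photoperiodic response-curve fitting yielding the critical
    night length (CNL) with bootstrap confidence intervals and
    latitude-cline correlation.  A seeded synthetic-data module generates
    all four input kinds with known ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
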