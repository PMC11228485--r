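Package: flysleepr
Title: Circadian Activity, Sleep and Arousal-Threshold Analysis for
    Drosophila Behavioral Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for behavioral chronobiology (ethomics) in Drosophila:
    reading Trikinetics-style activity monitor (DAM) files and
    video-tracking trajectories onto a zeitgeber time axis, circadian
    activity profiling (actogram profiles, peak phase, morning activity
    index, day/night totals, temperature-shift alignment), sleep scoring
    by the five-minute immobility rule, vibration and blue-light
    arousal-threshold, responder and sleep-latency analysis, shade and
    blue-light zone preference indices, and the aligned-rank-transform
    factorial ANOVA used in this literature.  A two-process (circadian
    clock plus sleep homeostat) synthetic fly simulator with warm (25 C)
    and diapause (10 C) parameter regimes provides ground-truth data so
    that every analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    car,
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
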