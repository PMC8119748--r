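Package: erpscene
Title: Simulation and Analysis of Scene-Complexity ERP Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for visual target-detection experiments with natural-scene
    stimuli and event-related potentials (ERPs). Covers quantitative stimulus
    screening (histogram entropy, gray-level uniformity, HSI brightness,
    vehicle size, iterative interquartile-range outlier removal) and oddball
    design assembly; EEG preprocessing (resampling, zero-phase band-pass and
    notch filtering, average re-referencing, epoching with baseline
    correction, joint-probability epoch rejection); ERP statistics over
    electrode clusters (pointwise FDR-corrected t-test traces, peak measures,
    the two-sample jackknife peak-latency test, performance-group splits);
    behavioral summaries and comparisons; and a seeded synthetic-data
    generator (textured stimulus patches, multi-channel EEG with occipital
    and centro-parietal components, behavioral records) so every stage can be
    verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
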