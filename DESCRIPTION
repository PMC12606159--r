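Package: sealvox
Title: Underwater Vocalization Analysis for Hawaiian Monk Seals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing low-frequency underwater vocalizations of
    Hawaiian monk seals recorded by passive acoustic monitoring. Provides
    band-limited power spectrograms and the standard suite of selection
    measurements (energy-percentile frequencies, bandwidths, peak frequency,
    aggregate entropy, frame-based signal-to-noise estimates), a rule-based
    call taxonomy (elemental and combinational call labels, bout
    segmentation), linear discriminant classification of call types with
    leave-one-out cross-validation and its derived statistics, diel
    calling-activity profiles with day/night rank-sum comparisons, and a
    seeded synthetic call generator so every stage of the pipeline can be
    exercised without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
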