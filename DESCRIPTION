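Package: harmbind
Title: Coincidence-Dependent Harmonic Integration Analysis for Auditory Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how auditory cortical populations bind
    multi-frequency sounds with synchronous onsets. Covers harmonic and
    onset-shifted stimulus construction, fundamental-frequency extraction from
    vocalization audio by harmonic template matching, two-photon calcium
    imaging response quantification (neuropil correction, dF/F,
    coincidence-preference and linearity indices), population geometry and
    non-negative matrix factorization clustering of onset-shift response
    profiles, noise-correlation subnetwork detection with matched controls,
    peristimulus time histogram and optogenetic suppression kinetics, and
    psychometric fitting of discrimination behavior. Includes ground-truthed
    synthetic data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    EBImage,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
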