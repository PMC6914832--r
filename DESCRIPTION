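Package: synergycube
Title: Muscle-Synergy Posture Classification and Intermittent Cube Control
    from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-muscle myoelectric control research: sliding
    root-mean-square envelopes of multichannel surface electromyography,
    extraction of muscle synergies from concatenated pairwise-posture
    envelopes by non-negative matrix factorization with multi-restart
    selection on the silhouette index, round-robin minimum-distance
    classification of static upper-limb postures, and simulation of an
    intermittent switched controller that drives a virtual sphere through
    second-order critically damped dynamics inside a normalized cube to
    reach targets. Includes a synthetic electromyography generator with
    posture-specific synergy structure, trial performance measures, and
    paired/independent t-test utilities for condition comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    yaml,
    optparse
Config/testthat/edition: 3
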