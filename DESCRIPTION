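Package: synkin
Title: Synapse Versus Kinapse Analysis of T-Cell Migration Tracks and Masks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the balance between stable immunological synapses and
    motile kinapses from single-cell centroid tracks, and measures the
    durability of T-cell interactions with micro-contact-printed stimulatory
    spots. Implements transient-confinement detection on tracks via a
    Simson-Saxton-type probability level, positional-spread classification of
    confined periods and the positional stability index; arrest detection,
    virtual synchronization and log-linear survival (half-life) fitting on
    spot grids; binary-mask sampling efficiency and protrusion index; a
    ground-truth-labelled two-state motility simulator; and group comparison
    reporting with paired t and Mann-Whitney U tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
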