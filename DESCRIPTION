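Package: msaptrio
Title: Parent-Hybrid Fingerprint Trio Analysis for AFLP and MSAP Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of dominant-marker fingerprints in
    parent-parent-hybrid trios. Classifies AFLP and cDNA-AFLP fragments
    into inheritance and loss classes, types CCGG-site cytosine
    methylation from paired HpaII/MspI (MSAP) lane profiles, builds
    mid-parent expectations, and tests hybrid methylation proportions
    against the mid-parent value with a pooled two-proportion U
    statistic. Includes a seeded synthetic-trio generator with ground
    truth so the whole pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
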