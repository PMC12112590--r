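Package: polwave
Title: Nascent-Transcription Wave Analysis and Pol II Kinetic Simulation
Version: 0.1.0
Authors@R:
    person("Polwave", "Maintainers", email = "maintainers@polwave.dev",
           role = c("aut", "cre"))
Description: Analysis of DRB-release nascent-RNA (TT-seq/Bru-seq) and Pol II
    ChIP-seq time courses: transcript filtering to long non-overlapping
    transcription units, TSS-anchored strand-oriented coverage matrices and
    metagene profiles, smoothing-spline localization of the advancing
    transcription wave, elongation-rate estimation by linear regression of
    wave positions over time after release, and a distal/proximal Pol II
    occupancy index operationalizing elongation processivity.  A stochastic
    simulator of promoter-proximally paused polymerases released at time
    zero -- constant elongation speed, exponential premature-termination
    hazard in distance, Poisson sequencing noise -- generates synthetic
    annotation, nascent and occupancy tracks with ground truth, so every
    pipeline stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
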