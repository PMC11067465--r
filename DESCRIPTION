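Package: schoolforces
Title: Agent-Based Schooling Models and Force-Map Inference for Collective Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-dimensional schools of self-propelled agents
    interacting through attraction-repulsion and alignment forces over
    Voronoi neighbor networks, including a selective-interactions variant
    in which individuals respond only to faster neighbors, an explicit
    antialignment variant driven by a tabulated force field, and a
    persistent-random-force variant. Provides force-map inference (binned
    mean accelerations in focal-frame relative-position and
    relative-velocity coordinates with conditional sample filters), group
    observables (polarization, nearest-neighbor distance, convex-hull area
    per capita, Voronoi contact durations, speeds, turning rates),
    surrogate self-delay force maps, and time-delayed orientation and
    speed correlations for leadership analysis, together with trajectory
    smoothing, Gaussian-derivative differentiation and perspective
    correction for experimental tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
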