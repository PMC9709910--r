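Package: tagcryst
Title: Crystallinity and Polymorph Metrics for Triacylglyceride Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies crystallinity in molecular dynamics trajectories of
    triacylglycerides (TAGs). Implements three complementary metrics:
    intramolecular distance criteria classifying each molecule as "parallel"
    (sn-1/sn-3 chains packed side by side) and "stretched" (spanning its full
    crystalline extension), the near-neighbor occupancy (NNO) count of common
    neighbors between subsequent frames, and a four-body unit-cell detector
    that distinguishes the beta-1 and beta-2 polymorphs from the rotation of
    the oleic-chain kink. Includes readers for GROMACS GRO coordinates and a
    plain-text trajectory format, periodic-boundary geometry with cell-list
    neighbor search, distance-band calibration against a reference crystal,
    and a synthetic lattice/trajectory generator so every metric can be
    validated without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
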