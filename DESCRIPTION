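Package: vfasense
Title: Nanomechanical Sensor Array Analysis of Volatile Fatty Acid Odors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signal modeling and discrimination pipeline for nanomechanical
    (membrane-type surface stress) sensor arrays measuring volatile fatty
    acid (VFA) odors, as used in silage quality assessment. Provides the
    closed-form injection/purge response model combining first-order
    sorption kinetics with viscoelastic stress relaxation, an independent
    ODE/hereditary-integral oracle, bound-constrained nonlinear
    least-squares extraction of kinetic parameters (diffusion time
    constant, relaxation time, modulus ratio), time-anchored feature
    extraction from rise and decay curves, standardized PCA with cluster
    separation scoring, and a seeded synthetic-data generator emulating a
    two-group silage headspace study with Raoult's-law water suppression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
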