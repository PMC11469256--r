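Package: rheodem
Title: In Silico Oscillatory Shear Rheometry of Frictional and Cross-Linked Particle Packings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional discrete-element "in silico rheometer" for dense
    suspensions of soft frictional grains. Builds seeded bidisperse packings,
    optionally cross-links neighboring grains into bulk networks, compact
    irregular particles, or loosely cross-linked porous particles, shears them
    with Lees-Edwards oscillatory boundary driving, measures the symmetric
    virial stress tensor, and extracts storage and loss moduli per strain
    amplitude. A feature-extraction layer reduces any amplitude sweep
    (simulated or imported from rheometer exports) to the characteristic
    signature of injectable granular biomaterials: low-strain plateau modulus,
    elastic softening transition, soft plateau stress, yield strain and
    relative yield stress.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
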