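Package: mandibeam
Title: Beam-Theory Biomechanics of the Crocodilian Mandible
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Structural analysis of crocodilian mandibles idealized as
    three-element 'Y'-shaped space frames. Provides a linear-elastic
    12-degree-of-freedom Euler-Bernoulli frame solver with fibre-stress
    recovery, canonical biting/shaking/twisting load cases with physically
    motivated load magnitudes (harmonic shake and rigid-body twist equations
    of motion, dry-skull muscle forces), landmark morphometrics (generalized
    Procrustes superimposition and shape PCA), and AICc-based selection among
    morphological predictors of peak strain, together with seeded synthetic
    generators for measurement sweeps, pseudo-taxa, landmark populations and
    element-strain fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
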