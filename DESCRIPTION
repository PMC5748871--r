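Package: arteryring
Title: Radial Dynamics of Hyperelastic Artery Ring Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the radial dynamic response of short human artery
    segments modeled as incompressible hyperelastic rings under pulsatile
    blood pressure. Implements three constitutive laws tied to vessel health
    (the Skalak membrane law for healthy hardening walls, the Hariton/Delfino
    exponential law for atherosclerotic stiffening, and Mooney-Rivlin
    softening for aneurysmatic walls) plus an equivalent linear model built
    on the initial tangent modulus. Provides dimensionless equations of
    motion, stiff time integration with energy-conserving peak extraction,
    response-spectrum parameter sweeps, radial resonance frequencies,
    strain-energy-density failure metrics, worked validation examples, and
    pulse-wave distension helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
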