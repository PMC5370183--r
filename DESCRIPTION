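Package: ztlkin
Title: Photocycle-Coupled Degradation Kinetics of Plant Clock Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic modelling of ZEITLUPE (ZTL) LOV-domain photochemistry
    coupled to light/dark-dependent degradation of the Arabidopsis clock
    proteins PRR5 and TOC1.  Provides the closed-form and numerical solution
    of the dusk-anchored degradation model in which the instantaneous
    degradation coefficient relaxes from the light-state rate k1 to the
    dark-state rate k2 with the LOV adduct-decay (dark-reversion) rate k3,
    piecewise simulation under light/dark schedules, monoexponential fitting
    of dual-wavelength absorbance dark-recovery traces, bounded nonlinear
    least-squares inference of degradation parameters from protein time
    courses with bootstrap confidence intervals and identifiability
    diagnostics, and a seeded synthetic-data generator with named presets for
    the characterised photocycle variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
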