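Package: sansrheo
Title: SANS and Rheology Analysis of Salt-Free Polyelectrolyte Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Staged fitting of reduced small-angle neutron scattering (SANS)
    profiles of semidilute polyelectrolyte solutions with a composite
    wormlike-chain/correlation-peak/low-q-upturn intensity model, steady-shear
    rheology analysis (Carreau fits, relaxation times, specific viscosity),
    piecewise power-law segmentation of the concentration dependence of the
    specific viscosity into semidilute unentangled, entangled and concentrated
    regimes, and closed-form polyelectrolyte scaling-theory calculators
    (Bjerrum length, Manning condensation, electrostatic blobs, correlation
    length, crossover concentrations) that link the scattering and rheology
    results. Includes a synthetic-data generator emulating a sodium
    carboxymethyl cellulose concentration series so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
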