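Package: polyionics
Title: Charge Density, Conformation and Cation-Interaction Analysis of Polyanion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing linear polyanions (polynucleotides,
    acidic polypeptides, glycosaminoglycans, polyphosphate and similar
    polyelectrolytes) from coordinate trajectories. Implements the
    decomposition of a polymer's charge distribution into a linear charge
    density along the backbone axis and a radial charge density about that
    axis; per-frame compactness metrics (end-to-end distance, radius of
    gyration, the mean-squared size ratio) and essential-dynamics principal
    component analysis of backbone anchor atoms; and counterion-organization
    statistics including radial distribution functions, bound-ion counts,
    charge-neutralization and cation-bridging fractions, residence times
    fitted from survival probabilities, and first-shell hydration numbers.
    A synthetic bead-chain generator with planted chain regimes, ion-binding
    shells and exponential dwell kinetics provides ground truth for every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
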