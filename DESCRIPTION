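Package: cakewash
Title: Mechanistic Filtration and Washing Models for Drug-Substance Isolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Integrated mechanistic modelling of active-pharmaceutical-ingredient
    isolation by dead-end constant-pressure cake filtration followed by cake
    washing. Filtration uses Darcy's law with a Carman-Kozeny specific cake
    resistance and is halted at dryland or breakthrough. Washing is modelled by
    six mechanisms of increasing complexity: pure displacement, perfectly mixed
    dilution, and diffusion-dispersion (as a 1-D advection-dispersion equation
    or a tanks-in-series cascade), each with or without solid-phase dissolution
    and deposition at solid-liquid equilibrium driven by binary-solvent
    solubility curves. Predicts wash curves, filtrate and cake composition,
    particle-size-distribution and porosity evolution, and product mass
    loss or gain, with model-selection guidance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
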