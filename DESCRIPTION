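Package: culturesim
Title: Agent-Based Simulation and Motion Analysis of Adherent Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of individual cell agents growing attached to
    a two-dimensional culture surface. Cell cycle progression and attachment are
    modelled as Markov chains whose transition probabilities combine logistic
    factor effects (serum, cell volume, local confluence, vitality, drugs) and
    are adapted to the simulation time interval; cell volume grows
    exponentially; movement follows a three-component model (random walk,
    directional persistence, bias) extended with cell-cell repulsion,
    self-generated attractant gradients and physical constraints. Plate-level
    events (medium changes, drug and attractant addition, scratch wounds,
    transfection, lytic viral infection) perturb running experiments. A
    companion analysis module estimates random/persistence/bias components,
    mean-squared-displacement curves with anomalous-diffusion and
    Fuerth-persistence fits, linearity, coherence and circular statistics from
    simulated or experimental cell tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    MASS,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
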