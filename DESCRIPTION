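Package: gprff
Title: Gaussian Process Regression Force Fields with Atomic Local Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learned force fields in which Gaussian process regression
    models, trained on per-atom energies and spherical-tensor multipole moments
    expressed in atomic local frames, replace the bonded and intramolecular
    electrostatic terms of a classical force field. Provides atomic-local-frame
    featurization of molecular geometries (3N-6 features with cyclic azimuths),
    a cyclic-corrected RBF kernel with concentrated log-likelihood hyperparameter
    optimization, active-learning training-set growth, spherical-tensor multipole
    electrostatics up to the hexadecapole with square rank truncation, a
    Lennard-Jones nonbonded term, a velocity-capped zero-Kelvin geometry
    optimizer, validation analytics (S-curves, Kabsch RMSD, dimer classification,
    hydrogen-bond geometry tables), and a fully analytic molecular-property
    surrogate so the whole pipeline can be exercised without external quantum
    chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
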