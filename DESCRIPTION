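Package: curvnp
Title: Implicit-Nanoparticle Curvature Restraints and Coarse-Grained
    Dynamics for Peptide Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models a nanoparticle of chosen size implicitly, as a pair of
    restraint potentials around a virtual sphere: an attractive spherical
    harmonic (shell) potential anchoring designated atoms (peptide
    N-termini, the NANO index group) to the surface, and a flat-bottom
    excluded-volume potential repelling the whole solute (the PEPTIDE
    group) from the particle interior.  Provides the placement geometry
    for setting up such systems, readers and writers for GROMACS GRO and
    NDX files and for the mdp user-parameter block that configures the
    model, VMD sphere-drawing commands for visualisation, a coarse-grained
    Go-type bead-chain representation of preformed fibril oligomers with a
    BAOAB Langevin integrator, and stability metrics (native-contact
    fraction, superposition RMSD, surface-displacement statistics) so that
    nanoparticle-size effects on oligomer stability can be explored at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
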