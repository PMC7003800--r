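Package: cringpmf
Title: Kinetic and Thermodynamic Simulation of the Chloroplast Proton Motive
    Force with Variable ATP Synthase c-Ring Stoichiometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the light reactions of higher-plant chloroplasts as a
    stiff system of ordinary differential equations in which the only varied
    factor is the number of c-subunits in the F0F1-ATP synthase rotor ring
    (and hence the H+/ATP ratio).  Provides closed-form thermodynamics of the
    proton motive force (pmf) and its partitioning into delta-psi and delta-pH,
    a delta-psi-dependent model of photosystem II charge recombination and
    singlet-oxygen production, pH-dependent photosynthetic control at the
    cytochrome b6f complex and qE-type nonphotochemical quenching, synthetic
    static / sinusoidal / square-wave illumination protocols at matched photon
    dose, and an experiment driver that sweeps c-ring sizes and reports
    cumulative linear electron flow and singlet-oxygen totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
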