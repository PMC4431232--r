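Package: nanomagsim
Title: Hybrid Spin/Molecular Dynamics of Magnetic Nanoparticle Assemblies
    and Magnetoresistive Biosensor Kinetics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation tool chain for nanoparticular magnetoresistive
    biosensors.  Models the self-assembly of magnetic dipolar nanoparticles
    in a viscous matrix by alternating stochastic Landau-Lifshitz-Gilbert
    spin dynamics (moment orientations at fixed positions) with overdamped
    Langevin molecular dynamics (positions at fixed moments) under
    dipole-dipole attraction and Weeks-Chandler-Andersen hard-sphere
    repulsion.  Provides a rotating damped-field demagnetization protocol
    for frustrated dipolar ensembles, magnetization curves under field
    sweeps, and the mapping from reduced magnetization to giant
    magnetoresistance.  A companion flow-cell module simulates protein
    transport over a DNA-functionalized sensor floor
    (advection-diffusion with a Robin reactive boundary coupled to a 1:1
    Langmuir surface rate law), generates sensorgrams, and recovers
    association/dissociation rate constants by exponential and one-site
    isotherm fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
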