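Package: hydroxff
Title: Scaled-Charge Hydroxide Force-Field Toolkit for TIP4P/2005 Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing nonpolarizable, scaled-charge
    (electronic-continuum-corrected) models of aqueous alkaline hydroxide
    solutions (LiOH, NaOH, KOH) in TIP4P/2005 water. Provides the hydroxide
    force-field parameter registry with Lorentz-Berthelot combination and
    explicit deviations, charge scaling, rigid-molecule templates and GROMACS
    topology fragments; molality-based solution-box composition and multi-frame
    GRO/PDB/XYZ input/output; an exact pair-potential evaluator (Lennard-Jones
    plus Coulomb with direct Ewald summation and analytic tail corrections) for
    small periodic systems; structural estimators (radial distribution
    functions, coordination and contact-ion-pair integrals, hydration numbers,
    distance-angle joint distributions, hydrogen-bond counts); and
    thermodynamic, transport and interfacial estimators (temperature of
    maximum density from cubic fits, Despretz group contributions,
    Einstein-relation diffusion with the Yeh-Hummer finite-size correction,
    Green-Kubo shear viscosity, virial-route surface tension, Gibbs surface
    excess, direct-coexistence freezing-point bracketing and picnometer
    densimetry). Synthetic fixture generators with analytically known ground
    truth support verification of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
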