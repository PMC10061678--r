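Package: mlmm
Title: Electrostatic Embedding of Machine-Learned Potentials in Point-Charge
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the electrostatic embedding energy of a neutral H/C/N/O/S
    molecule placed in a mesh of molecular-mechanics point charges, decomposed
    into a static term from Slater core+valence atomic densities, an induced
    term from Thole-damped atomic dipoles, and the polarization cost. Atomic
    charges come from charge equilibration (QEq) over learned
    electronegativities; per-atom valence widths and electronegativities are
    supplied by sparse Gaussian-process regression over SOAP atomic-environment
    descriptors with an Informative-Vector-Machine basis. Includes the full
    four-stage training workflow against reference per-atom densities and
    molecular dipolar polarizabilities, a synthetic-data generator for
    statistically realistic training tables, and quadrature oracles for every
    analytic potential.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
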