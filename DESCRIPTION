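Package: eemcc
Title: Energy-Entropy Binding Free Energies by Multiscale Cell Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-point ("energy-entropy") binding free energies for host-guest
    systems from force-bearing molecular dynamics trajectories. Entropy is
    computed with the multiscale cell correlation (MCC) decomposition:
    vibrational terms from quantum-harmonic-oscillator frequencies obtained
    as eigenvalues of mass-weighted force and moment-of-inertia-weighted
    torque covariance matrices at the molecule and united-atom levels, and
    topographical (minima-counting) terms for position, orientation and
    conformation. First hydration shells are identified with the
    parameter-free relative angular distance (RAD) criterion and water is
    book-kept into shell and released-to-bulk categories with exact
    stoichiometry. Four simulations (host, guest, complex, bulk water)
    combine into a standard binding free energy with replicate error
    statistics. Includes a synthetic-fixture generator with analytic ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
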