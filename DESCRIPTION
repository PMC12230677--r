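Package: qdrcharges
Title: Quadrupole-Dipole Resorption of Atom-in-Material Multipoles into Point Charges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adjusts stockholder-partitioned atom-centered point charges by
    partly resorbing atom-in-material dipole and quadrupole moments into the
    charge values while exactly preserving the system's net charge, total
    dipole moment, and total traceless quadrupole moment about any origin.
    Provides the multi-pass quadrupole-then-dipole resorption driver built on
    matrix-free per-atom conjugate-gradient block solves, molecular multipole
    error metrics under both traceless-quadrupole conventions, grid-based
    electrostatic-potential RMSE/RRMSE evaluation with valid-point selection
    (including Ewald sums for 3-D periodic charge models and Gaussian cube
    I/O), conformational-ensemble figures of merit, and a synthetic-fixture
    generator so the whole stack is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
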