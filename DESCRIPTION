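Package: cascd
Title: Second-Order CASSCF with Cholesky-Decomposed Two-Electron Integrals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Norm-extended optimization (NEO) for complete active space
    self-consistent field (CASSCF) wave functions, built on a
    threshold-controlled pivoted Cholesky decomposition of the electron
    repulsion integrals. Provides determinant-based full CI in the active
    space with Davidson diagonalization, reduced density matrices,
    Cholesky-based Fock and Q-matrix builds, direct Hessian-vector
    products with one-index-transformed integrals, an augmented-Hessian
    trust-region macro/microiteration driver, restricted and unrestricted
    SCF with triplet-instability-driven unrestricted-natural-orbital
    (UNO) active-space selection, FCIDUMP input/output, and model
    Hamiltonian generators (Hubbard chains, Pariser-Parr-Pople pi
    systems, random low-rank integral fixtures) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
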