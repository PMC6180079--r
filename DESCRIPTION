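Package: rbmqs
Title: Three-Layer Restricted Boltzmann Machine Solver for Molecular
    Qubit Hamiltonians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Variational ground-state solver for second-quantized
    electronic-structure Hamiltonians mapped to qubits by the
    Jordan-Wigner transformation.  A restricted Boltzmann machine
    amplitude with an additional tanh sign layer serves as the trial
    wavefunction; training minimizes the energy expectation with
    covariance-based gradients, either by exact enumeration of the basis
    or from samples, including a classical simulation of a
    controlled-rotation Gibbs-sampling circuit with rejection and
    power-k post-processing.  Ships an FCIDUMP reader with active-space
    reduction, a plain-text Pauli Hamiltonian format, synthetic fixture
    generation, potential-energy-surface scans with transfer-learning
    warm starts, qubit resource accounting, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
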