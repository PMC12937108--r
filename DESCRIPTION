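Package: vibronmps
Title: Vibronic Quantum Dynamics with n-Mode Hamiltonians and Matrix Product States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds n-mode expansions of anharmonic potential energy surfaces and
    nonadiabatic couplings, quantizes them in per-mode modal bases by numerical
    quadrature, and assembles the resulting second-quantized vibronic Hamiltonian
    as a term list over a tensor-train lattice with electronic head sites and
    composite vibrational operators. Provides matrix product operator compilation,
    U(1)-symmetric matrix product states, two-site ground-state DMRG, tangent-space
    two-site time-dependent DMRG propagation, and Franck-Condon observables
    (autocorrelation functions, diabatic electronic populations, absorption
    spectra), together with a dense exact-diagonalization oracle for verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
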