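Package: conikit
Title: Pseudodiabatic Surrogate Models for Minimum-Energy Crossing Point
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates minimum-energy crossing points (MECPs) between two
    electronic potential energy surfaces using a smooth pseudodiabatic
    surrogate model. Adiabatic energies, gradients and nonadiabatic
    couplings from a pluggable backend are converted, through a gauge-fixed
    two-state diabatization, into three smooth surfaces (alpha, beta, gamma)
    which are interpolated by gradient-enhanced Kriging with a Matern-5/2
    kernel and analytic derivatives. A restricted-variance optimizer then
    walks the surrogate under an energy-difference constraint, calling the
    backend once per macroiteration. Ships analytic two-state model
    Hamiltonians with known crossing seams for testing and benchmarking,
    XYZ geometry input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
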