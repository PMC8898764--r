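Package: hdespin
Title: Heisenberg Double-Exchange Spin-State Analysis for Mixed-Valent Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Electronic-structure analysis tools for mixed-valent d5-d6
    dimers such as [Fe2Q2]+ (Q = S, Se, Te) clusters. Builds the Heisenberg
    double-exchange spin ladder and its ground-spin phase diagram, extends
    it with Piepho-Krausz-Schatz (PKS) vibronic coupling to adiabatic
    potential surfaces with Robin-Day well classification, simulates and
    fits van Vleck molar susceptibility (chi*T) curves over the
    double-exchange ladder, computes powder magnetization with zero-field
    splitting by full spin-Hamiltonian diagonalization, and derives
    effective g values, rhombograms, nutation frequencies and doublet
    populations for half-integer-spin EPR analysis. Includes a
    seed-controlled synthetic magnetometry data generator for end-to-end
    testing of the fitting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
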