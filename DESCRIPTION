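Package: macroquant
Title: Macroscopic Quantum-Type Potentials and Scale-Law Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numerical toolkit for macroscopic Schrodinger-type dynamics
    governed by a system-specific constant D in place of hbar/2m: stationary
    states and unitary time evolution on 1-3 dimensional grids (with an
    optional Ginzburg-Landau nonlinearity), exact interconversion among the
    equivalent wave, hydrodynamic (Madelung + quantum potential), two-fluid
    and diffusive (Fokker-Planck + Q+) representations, scale-space laws
    (fractal lengths, log-periodic corrections, scale dynamics, scale
    oscillator and limiting-scale laws) with log-periodic fitting, and
    application layers for morphogenesis (spherical-harmonic growth shapes,
    duplication, scale hierarchies), Lagrangian turbulence corrections and
    dopant-trap bound states. Includes seeded synthetic-fixture generators
    and a plain-text field container for reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
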