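Package: dysonspec
Title: Dyson Orbitals and Simulated Time-Resolved Photoelectron Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Computes Dyson orbitals and Dyson norms between
    configuration-interaction wavefunctions of an n-electron molecule and
    its (n-1)-electron cation, including decomposition of spin-adapted
    configuration state functions into Slater determinants, coefficient
    screening, and non-orthogonal molecular-orbital sets. Builds static
    ground- and excited-state photoelectron spectra from binding energies
    and Dyson norms, samples nuclear initial conditions from the
    ground-state harmonic Wigner distribution, assembles time-resolved
    photoelectron spectra (TRPES) from surface-hopping trajectory
    ensembles with decomposition by electronic state, mechanistic pathway
    and tautomer, and extracts excited-state lifetimes by mono- and
    global exponential fitting. A synthetic-data module generates toy
    wavefunction pairs, harmonic models and trajectory ensembles with
    known lifetimes so the whole pipeline can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
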