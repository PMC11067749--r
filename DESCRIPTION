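Package: aspherED
Title: Aspherical-Atom Electron Diffraction Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transferable aspherical atom model (TAAM) refinement machinery for
    3D electron diffraction. Implements Hansen-Coppens multipole pseudoatom
    densities and their analytic X-ray form factors, Mott-Bethe conversion to
    electron scattering factors, kinematical structure factors with anisotropic
    displacement parameters, weighted least-squares refinement of structural and
    multipole parameters, N-beam Bloch-wave dynamical intensities with
    precession averaging and crystal-thickness refinement, residual
    electrostatic potential maps with fractal-dimension analysis, and a
    synthetic-data generator emulating a 1-methyluracil-like molecular crystal
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
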