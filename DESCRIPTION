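Package: shiftfieldr
Title: Shift-Field Refinement of Crystallographic Models and Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-atomic, grid-parameterized refinement of macromolecular
    models against X-ray diffraction data. For every point of an
    electron-density map, the shifts to positional and isotropic
    displacement (B-factor) parameters, plus a constant offset, that best
    explain a difference map within a surrounding spherical region are
    obtained by weighted least-squares regression, computed efficiently by
    FFT convolution of gradient-product maps with a radial kernel. The
    resulting shift field can be applied to an atomic model by
    interpolation or to a density map by resampling (morphing). Includes a
    Gaussian-atom density engine, structure-factor scaling and R factors,
    a refinement driver implementing the iterative constant-U protocol,
    radius sweeps, synthetic toy-crystal generators for fully reproducible
    testing, and readers/writers for PDB, plain-text reflection files and
    CCP4/MRC maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
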