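Package: pericarreau
Title: Peristaltic Flow of a Variable-Viscosity Carreau Fluid in a
    Flexible Annulus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Semi-analytic model of peristaltic transport of a Carreau
    shear-thinning fluid in the annular gap between a rigid catheter and a
    sinusoidally waving elastic outer wall, in the long-wavelength,
    low-Reynolds-number regime. Provides closed-form temperature and
    Soret-coupled concentration fields in real modified Bessel form, a
    double perturbation expansion of the axial velocity in the Weissenberg
    number and the viscosity-variation coefficient, stream-function and
    trapped-bolus diagnostics, and an independent nonlinear flux-shooting
    solver used to validate the expansion and measure its remainder order.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
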