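Package: viscoind
Title: Simulation and Analysis of Viscoelastic Indentation Force Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of displacement-controlled indentation of
    linear viscoelastic materials using the Lee-Radok and Ting hereditary
    integral solutions for cylindrical, spherical and conical probes under
    triangular and sinusoidal ramps. Provides a catalogue of classical and
    fractional relaxation functions (spring, dashpot, Kelvin-Voigt, Maxwell,
    standard linear solid, generalized Maxwell, springpot and its
    combinations) with Mittag-Leffler numerics, Prony series approximation,
    and analysis tools that extract the apparent Young's modulus, the
    normalized hysteresis area and the force-curve exponent from simulated or
    measured force curves, including their dependence on the indentation
    time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
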