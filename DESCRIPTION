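Package: afsrheo
Title: Acoustic Force Spectroscopy Calibration and Multi-Oscillation Microrheology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and analysis tools for active microrheology with
    acoustic force spectroscopy (AFS). Implements Stokes force calibration of
    acoustic forces on microspheres near a wall with Brenner's exact
    perpendicular wall-drag correction, conversion of piezo drive amplitude to
    force through spatially resolved calibration maps, multi-frequency
    oscillatory (mOsc) microrheology yielding the complex shear modulus
    G*(omega) by per-frequency Fourier demodulation in sliding time windows,
    and fractional viscoelastic model fitting (single fractional element and
    generalized Kelvin-Voigt) with bootstrap confidence intervals. A seeded
    forward simulator generates calibration traces, spatial calibration
    fields and bead-on-cell oscillation experiments so the full pipeline can
    be exercised without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
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
RoxygenNote: 7.3.3
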