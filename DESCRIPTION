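Package: kaifluor
Title: Deconvolution and Rhythm Analysis of KaiC Tryptophan Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing rhythmic tryptophan-fluorescence readouts of
    the cyanobacterial KaiC circadian oscillator. Apparent band-integrated
    fluorescence is modelled as a linear combination of the four Ser431/Thr432
    phosphorylation states (ST, SpT, pSpT, pST); the package fits per-state
    intensities by least squares, extracts the contribution of an engineered
    tryptophan probe (W419) by construct subtraction, forward-simulates
    oscillating fluorescence, processes emission spectra (NATA/concentration
    normalization, 320-370 nm band integration, sub-grid emission-maximum
    estimation, difference spectra), and quantifies rhythms by cosine-Fourier
    period fitting and Arrhenius temperature-compensation analysis (activation
    energy and Q10). A synthetic-data generator emulates phosphostate
    relaxation and oscillation kinetics, state-dependent emission bands, and
    measurement noise so the whole pipeline is testable without instrument
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
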