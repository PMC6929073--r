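Package: qclspec
Title: Simulation and Chemometric Analysis of Pulsed Quantum Cascade
    Laser Mid-Infrared Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end synthetic study of multianalyte quantification by
    tuneable pulsed quantum cascade laser (QCL) absorption spectroscopy in the
    1200-925 cm-1 fingerprint region, in both attenuated total reflection (ATR)
    and direct transmission configurations. Provides a 2-D ray tracer for
    trapezoidal ATR prisms with evanescent-field penetration and interaction
    length calculations, an A-optimal Scheffe mixture design generator for
    aqueous glucose/albumin/urea/lactate solutions, a pulse-resolved instrument
    simulator with laser and detector noise, the signal-processing chain (pulse
    binning, scan averaging, chi-squared spectral alignment, absorbance
    ratioing, noise characterisation), and NIPALS partial least-squares
    regression with leave-one-out, leave-five-out, and leave-one-series-out
    cross-validation reporting RMSECV and R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
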