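Package: tensionfret
Title: Quantitative FLIM-FRET Tension-Sensor and FCS Calibration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular tension-sensor experiments at
    developing muscle attachment sites. Fits time-correlated single photon
    counting (TCSPC) fluorescence decay histograms (monoexponential tail fits
    and fixed-lifetime biexponential fits) to obtain donor lifetimes, FRET
    efficiencies and the fraction of mechanically engaged sensor molecules;
    fits fluorescence correlation spectroscopy (FCS) autocorrelation curves
    (triplet/dark-state plus one- or two-component 3D diffusion models) to
    calibrate the confocal detection volume and molecular brightness; converts
    photon-count confocal images into absolute concentration maps and membrane
    surface densities, and combines them into tissue-stress estimates;
    quantifies FRAP recovery (mobile fraction, half time) and post-ablation
    recoil velocities from kymographs. Includes synthetic-data generators with
    attached ground truth for every input modality so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
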