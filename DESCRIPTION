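Package: vsfgmap
Title: Director Maps and Domain Textures from Phase-Resolved Vibrational
    Sum-Frequency Generation Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for heterodyne (phase-resolved) vibrational
    sum-frequency generation (vSFG) microscopy of lipid monolayers.
    Converts per-pixel time-domain interferogram stacks into complex
    spectral image cubes, normalises them against a z-cut quartz
    reference, separates out-of-plane (0-fold) and in-plane (1-fold)
    responses by azimuthal Fourier decomposition of a sample-rotation
    series, extracts absolute in-plane molecular director maps from the
    1-fold phase, deconvolutes CH2/CH3 resonances with Lorentzian line
    shapes, segments liquid-condensed domains, estimates relative lipid
    density and orientational order, and classifies mesoscale director
    textures (parallel, radial, spiral; clockwise or anti-clockwise; real
    or virtual boojum). A physics-based synthetic-data generator provides
    ground-truth scenes so every stage is verifiable without experimental
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
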