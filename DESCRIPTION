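Package: mosaicHSI
Title: Simulation and Learned Demosaicking of Snapshot Mosaic Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for snapshot mosaic hyperspectral imaging. Simulates 2D
    mosaic snapshot frames from high-spectral-resolution reflectance hypercubes
    using a physical sensor model (Lorentzian Fabry-Perot band responses,
    parasitic cross-talk, spatial subsampling through an n-by-n multispectral
    filter array), demosaicks them back to hypercubes with a bilinear baseline
    and a residual U-Net super-resolver with embedded spectral correction,
    converts spectra to sRGB via CIE XYZ under D65, and evaluates
    reconstructions with L1, PSNR, SSIM and a pluggable perceptual score.
    Includes a synthetic tissue-like phantom generator so the full pipeline is
    testable without external datasets, plus ENVI/TIFF/YAML interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
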