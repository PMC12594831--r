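Package: tripai
Title: Trimodal Photoacoustic, Ultrasound and Fluorescence Imaging Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis chain for a coaxial trimodal imaging probe
    built around a 64-element transparent ultrasound transducer array: digital
    phantoms with blood and indocyanine-green filled vessels, raw photoacoustic
    and steered line-beam ultrasound channel-data simulation, delay-and-sum
    image reconstruction, depth-wise fluence compensation, pseudo-inverse
    multispectral unmixing into Hb/HbO2/ICG with oxygen-saturation mapping,
    mosaic 3-D volume stitching and projections, voxel Monte Carlo photon
    transport for illumination-geometry comparison, and transducer/image
    metrology (resonance coupling coefficient, bandwidth, crosstalk, FWHM,
    CNR, pulsation spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    tools,
    utils,
    yaml,
    jsonlite,
    RNifti,
    tiff,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
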