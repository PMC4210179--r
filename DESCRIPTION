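Package: canopylight
Title: Three-Dimensional Seagrass Canopy Light Capture and Photosynthetic
    Saturation Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds virtual canopies of a branched, strap-leaved seagrass
    (Amphibolis-like morphology) at controlled leaf area index, flexes them
    under a simple oscillatory wave-force model, propagates an hourly
    clear-sky and plane-parallel water-column light field through the canopy
    with a geometric-optics multiple-scattering (radiosity) solver on a
    horizontally periodic scene, and reduces per-leaf photosynthetically
    available radiation to canopy-scale saturation metrics: the percentage of
    leaf area at or above the saturating irradiance E_k, the diurnal
    time-integral H^A_sat, and isocline surfaces over leaf area index and
    shading.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
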