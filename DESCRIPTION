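Package: hdrplan
Title: Inverse Dwell-Time Optimization for 3D HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gradient-based inverse treatment planning for high-dose-rate
    (HDR) brachytherapy. Builds a TG-43 point-source dose kernel over
    voxelized regions of interest, minimizes a quadratic one-sided
    dose-objective function with a per-channel minimum-anchored dwell-time
    modulation term under box constraints (L-BFGS-B), and evaluates plans
    with dose-volume histogram metrics (D_x%, V_y%, D_zcc), prescription
    normalization to target D90%, and dwell-time spread statistics.
    Includes a synthetic phantom generator emulating Fletcher-style and
    related gynecological applicator geometries so the full pipeline runs
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
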