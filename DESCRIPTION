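Package: rotorpose
Title: Single-Camera 3D Pose Reconstruction and Flow Diagnostics for
    Magnetically Levitated Pump Impellers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the three-dimensional pose (center, axis tilt,
    blade angle) of a magnetically levitated centrifugal blood-pump
    impeller from single-camera observations of fluorescent marker
    channels embedded in the blades, decomposes the pose time series
    into shift, mean-tilt and synchronous-precession motion modes, and
    provides the accompanying flow diagnostics: phase-binned averaging
    of planar velocity fields with normalized error statistics,
    power-spectral-density detection of non-ideal rotation modes in
    integral pump signals, and flow-regime formulas (viscosity model,
    Reynolds numbers, turbulence boundary-condition estimates). A
    synthetic forward model of the marker/laser geometry, camera frames,
    swirling velocity fields and harmonic integral signals makes the
    whole inverse pipeline testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
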