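Package: rfcurrent
Title: Measuring RF Currents Induced in Wire-Like Implants from Low-SAR MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the radiofrequency current induced in a wire-like
    implant (such as a deep brain stimulation lead) during MRI, from four
    magnitude images of a dual-angle high-dynamic-range actual flip-angle
    (da-hdrAFI) B1-mapping acquisition. Provides a quasi-static forward model
    of the transmit field around a straight wire at arbitrary angulation to
    B0, steady-state AFI signal equations with a Bloch-simulated slice-profile
    dictionary, sub-voxel oversampled patch synthesis, inversion of the model
    by differential evolution to estimate the wire current, and translation of
    fitted currents into per-configuration heating predictions and B1rms
    exposure limits via an implant-specific calibration constant. Includes a
    synthetic-data generator (noisy signal patches and thermometry time
    courses) so the full pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
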