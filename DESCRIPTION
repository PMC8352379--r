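Package: pttherm
Title: Thermal Kinetics Analysis for Photothermal Therapy Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for infrared-thermography recordings of
    laser-induced tumor heating in plasmonic photothermal therapy
    experiments. Extracts hotspot region-of-interest temperature traces
    from temperature-calibrated thermograph stacks, fits the step
    response of a first-order thermal system to estimate heating time
    constants with confidence intervals, and derives treatment metrics
    (maximum temperature, temperature change, effective temperature
    enhancement, heating efficiency, normalized heating curves) with
    group-level statistical comparison of nanoparticle-injected versus
    saline-control tumors. Includes a synthetic thermograph generator
    that emulates an eight-group (four near-infrared wavelengths by two
    injection arms) study design so the full pipeline can be exercised
    and validated without access to raw thermal video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
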