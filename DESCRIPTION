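Package: qctcal
Title: Internal (Phantomless) Density Calibration for Quantitative CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts computed tomography (CT) Hounsfield units into
    water-equivalent density images without a calibration phantom. The
    effective scan energy is estimated from tissue regions of interest
    (air, adipose, blood, skeletal muscle, cortical bone) by relating
    measured Hounsfield units to reference mass-attenuation curves, and
    the fitted affine map is used to produce muscle density in g/cm^3.
    Also provides reference-phantom calibration (sucrose-water or
    hydroxyapatite rods), a synthetic scan generator with known ground
    truth for validation, and agreement statistics (Bland-Altman limits
    of agreement, regression comparison, coefficient-of-variation tables
    across scan conditions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
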