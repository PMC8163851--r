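Package: pyroloss
Title: Matched Case-Control Analysis of Fire-Sourced PM2.5 and Pregnancy Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for self-comparison (mother-matched) case-control studies of
    gestational exposure to fire-sourced fine particulate matter (PM2.5).
    Implements calibration and source decomposition of paired chemical-transport
    model simulations against an annual satellite PM2.5 reference,
    inverse-distance-weighted downscaling, gestational-window exposure
    averaging, construction of mother-matched case-control sets with
    sensitivity-analysis subsets, conditional logistic regression fitted from
    the exact conditional likelihood with spline covariate adjustment, subgroup
    interaction and nonlinear exposure-response models, and attributable-fraction
    impact accounting for fire versus non-fire PM2.5. A synthetic-world generator
    produces gridded environmental fields and reproductive histories with the
    statistical structure the design assumes, so the full pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    ncdf4,
    yaml,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
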