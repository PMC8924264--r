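Package: tendrilcoil
Title: Two-Rule Kinematic Model of Tendril Coiling and Marker-Track Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the diameter-dependent coiling response of climbing-plant
    tendrils with a quasi-static planar model built from two behavioural rules
    (coiling starts around the contact point, and a minimum coiling angle is
    always attained once coiling starts), classifies simulated trials into the
    three-step phase decision tree (continuous coiling or moving contact point;
    tip contact or clip-shape coiling; success or detachment), and provides the
    matching measurement pipeline for marker-based 3D motion-tracking data:
    discrete bending-angle series, rapid-coiling/stop-stage segmentation, and
    stop-stage coil-diameter estimation by plane-projected circle fitting.
    Includes seeded generators for synthetic marker tracks and coiling-success
    tables, and a binomial generalized linear model (logistic regression via
    iteratively reweighted least squares) for the effect of support diameter
    and tendril length on coiling success.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
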