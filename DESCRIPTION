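Package: fdbraid
Title: Braided Flow-Diverter Mesh Geometry and Aneurysm Occlusion Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the relation between braided flow-diverter
    mesh morphology and cerebral aneurysm occlusion. Provides closed-form
    unit-cell porosity and braiding-angle geometry, centerline-based vessel
    models, virtual deployment of braided devices with foreshortening and
    curvature-driven mesh modulation, a principal-component aneurysm
    morphology index (MAAI), logistic occlusion models, time-to-occlusion
    ANCOVA with sequential covariate correction, and a seed-deterministic
    synthetic vessel/cohort generator with known ground truth for
    verification studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
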