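Package: pauhemo
Title: Hemodynamic Comparison of Endovascular Treatments for Penetrating Aortic Ulcer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare thoracic endovascular treatment strategies for
    penetrating aortic ulcer (PAU) on synthetic aortic geometries. Provides a
    parametric generator of thoracic-aorta surface meshes in three treatment
    configurations (untreated, single-branched stent graft, hybrid
    carotid-subclavian bypass), centerline morphometry of the left subclavian
    branch (cross-section diameters and areas, bifurcation angle, tortuosity),
    three-element Windkessel outlet calibration and area-ratio distribution, a
    lumped-parameter vascular network solver for flow splits and pressure
    drops, and wall-shear-stress indicator maps (TAWSS, OSI, ECAP) with
    exposed-area statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
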