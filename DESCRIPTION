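Package: dopmtools
Title: Optical Modelling and Volume Processing for Dual-View Oblique
    Plane Microscopy
Version: 0.1.0
Authors@R:
    person("dOPM", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and measurement tools for dual-view oblique plane
    microscopy (dOPM). Provides geometric collection-efficiency models
    based on solid-angle intersections of objective collection cones, a
    full vectorial Jones-matrix ray-tracing simulator of the folded
    collection path (polarizing beam splitter, quarter-wave plate double
    pass and coated tilted mirror with thin-film complex reflectivity),
    an equal-signal light-dose comparison between widefield z-stack and
    dual-view light-sheet acquisition, deskew/registration/fusion of
    sheared oblique image stacks, PSF and optical-sectioning metrology
    from bead and thin-sheet volumes, and deterministic synthetic data
    generators so every pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
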