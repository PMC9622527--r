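Package: aortaflow
Title: Conduit and Reservoir Function of Arteries from 4D Flow Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive assessment of the conduit and reservoir function of
    large arteries from time-resolved three-dimensional (4D flow) velocity
    fields and a lumen segmentation. Conduit function is quantified through
    the work-energy relative pressure decomposition (kinetic, advective and
    viscous components), the simplified advective pressure at a cross
    section, and the laminar viscous energy-loss rate. Reservoir function is
    quantified through foot-to-foot pulse wave velocity of flow waveforms
    along the vessel centreline and the Moens-Korteweg elastic modulus.
    Includes centreline extraction with curvature, diameter and wall
    thickness profiling, four-segment aortic subdivision from anatomical
    landmarks, body-surface-area indexing, analytic flow phantoms
    (Poiseuille, Womersley, tapered plug, propagating wave, torus) with
    closed-form ground truth for validation, and a cohort comparison layer
    with a Shapiro-Wilk normality gate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
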