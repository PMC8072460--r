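Package: pvshemo
Title: Hemodynamics of the Portal Venous System Before and After Splenectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric idealized geometry of the portal venous system (portal,
    splenic, superior/inferior mesenteric and left gastric veins), a steady
    incompressible Navier-Stokes solver with shear-thinning Carreau blood
    rheology on an immersed-boundary Cartesian grid, and wall-shear-stress
    post-processing (space-averaged WSS and the low-WSS area ratio ALS) for
    comparing pre- and post-splenectomy flow conditions across anatomical and
    morphogeometrical variants. Includes a reduced-order Poiseuille network
    model of the same vascular tree as a fast screening tool and cross-check,
    plus a scenario orchestrator that runs the full sensitivity study matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
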