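Package: octffr
Title: Coronary Fractional Flow Reserve Simulation from Intravascular
    Lumen Geometry and Vessel-Length Boundary Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Desk-scale simulator of coronary fractional flow reserve (FFR)
    from OCT-pullback-like lumen geometry. Lumped-parameter boundary
    conditions for the coronary microvasculature and veins are calibrated
    from angiographic vessel lengths (flow split proportional to subtended
    vessel length, resting coronary flow as a fraction of cardiac output),
    side-branch losses upstream of the imaged segment are folded into a
    resistance amplification factor from a radius-flow scaling law, and a
    quasi-1D cross-section-averaged solver of the imaged segment is coupled
    iteratively to an ODE microvascular network with intramyocardial
    compression and pressure-triggered collateral flow. Includes a synthetic
    pullback generator, hyperemia modelling, and method-agreement statistics
    (Bland-Altman, correlations, diagnostic confusion at the clinical
    FFR cutoff).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
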