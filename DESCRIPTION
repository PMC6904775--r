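Package: fumet
Title: Kinetic Modeling of 5-Fluorouracil Metabolism in Yeast Under ATP Depletion
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles and simulates a 22-reaction, 16-species kinetic model of
    5-fluorouracil (5-FU) salvage metabolism in Saccharomyces cerevisiae with
    Michaelis-Menten and reversible Ping Pong Bi Bi rate laws, under either a
    forced (fitted) ATP depletion curve or a dynamic ATP/ADP pool. Provides
    weighted-least-squares parameter estimation by multi-start Hooke-Jeeves
    pattern search with per-parameter fit statistics, metabolic control
    analysis (elasticities, flux and concentration control coefficients with
    summation-theorem verification), Hill dose-survival (EC50) fitting, an NMR
    linewidth-to-relaxation helper, and generators of synthetic 19F/31P
    NMR-style time courses and dose-survival tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    minpack.lm,
    MASS,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
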