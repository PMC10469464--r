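Package: pfastmf
Title: Chemical Activity-Based Trophic Magnification of Perfluoroalkyl
    Substances in Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing trophic magnification of perfluoroalkyl
    substances (PFAS) in food webs on a thermodynamically consistent basis.
    Implements tissue-phase partitioning from protein-water and membrane
    lipid-water distribution coefficients, QSPR prediction of missing
    coefficients from molar volume, apparent chemical activity with a
    fugacity-ratio correction for solids, five alternative concentration
    normalizations (wet weight, total protein, albumin, polar lipid, total
    lipid), regression-on-order-statistics summaries for left-censored
    measurements, maximum-likelihood censored regression of log
    concentration on trophic position to estimate trophic magnification
    factors (TMF = e^slope), and a synthetic food-web generator for
    end-to-end validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
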