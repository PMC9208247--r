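Package: bsasirt
Title: Graded Response Model Calibration and Scoring for the Bergen
    Shopping Addiction Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Item-response-theory calibration of short polytomous screening
    instruments, built around the 7-item Bergen Shopping Addiction Scale
    (BSAS).  Implements Samejima's graded response model with Bock-Aitkin
    marginal maximum likelihood EM estimation (including an equal-slope
    Rasch-type restriction), item and test information functions with
    conditional standard errors, Lord-Wingersky summed-score likelihoods,
    summed-score EAP conversion tables with SD-band risk cut-offs, local
    dependence and summed-score item-fit diagnostics, anchored Wald tests
    for differential item functioning across groups, and a seeded generator
    of BSAS-like synthetic cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
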