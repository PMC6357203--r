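Package: plateletdiv
Title: Quantifying Platelet Division by Differential Doublet Counting
    and Dye Dilution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical and image-analysis tools for quantifying the
    division of blood platelets cultured in semisolid medium. Implements
    the binomial null model for the colour composition of platelet
    doublets in two-colour mixing experiments, a one-sided tail test for
    depletion of two-colour doublets, and a closed-form estimator of the
    per-colour division fraction from singlet and doublet counts, with
    percentile-bootstrap confidence intervals. Also provides a synthetic
    semisolid-culture simulator (expectation-level, stochastic and
    spatially explicit, with rendered two-channel fluorescence fields),
    a spot-detection and proximity-clustering front-end that turns field
    images into count tables, and a dye-dilution (CFSE) quantifier for
    generation analysis of fluorescence event lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
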