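Package: petalmetry
Title: Petal Morphometrics and Allometric Scaling of Corolla Area
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures petal area, length and width from binary silhouette
    images or boundary-coordinate files, aggregates petals into per-flower
    corolla descriptors following the Koyama-Smith construction, and fits
    and compares the Montgomery equation (A = k*LW), the
    Montgomery-Koyama-Smith equation (A_T = k_KS*L_KS*W_KS) and a power-law
    alternative (A_T = beta*(L_KS*W_KS)^alpha) by log-scale ordinary least
    squares, with RMSE, AIC, percent-error model selection and bootstrap
    confidence intervals. Includes a synthetic two-species petal generator
    with known ground truth for end-to-end validation, and Tukey HSD
    comparisons of trait means between species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    readr,
    rlang,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
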