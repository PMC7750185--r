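Package: colstab
Title: Bootstrap Stability Selection for Colostrum Bacteriology Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking and modelling bacterial contamination of
    bovine colostrum on dairy farms. Implements threshold-based failure
    classification of total bacterial counts and coliform counts, a
    maximum-likelihood random-intercept (farm) linear mixed model with
    AIC-based backward elimination, and the bootstrapped stability-selection
    procedure that summarises, over resampled model fits, how often each
    management variable is retained together with mean coefficients,
    percentile bootstrap confidence intervals and bootstrap p-values. A
    synthetic herd-data generator with known ground truth supports recovery
    testing, and diagnostic helpers cover repeated k-fold cross-validation,
    predictor correlation screening, likelihood-ratio interaction screening
    and a conventional detectable-difference power calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
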