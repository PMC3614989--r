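Package: pelagifec
Title: Reproductive Dynamics and Potential Annual Fecundity of Pelagic Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for the reproductive biology of broadcast
    spawning pelagic fishes, built around South Pacific albacore tuna.
    Implements histological classification of ovaries into reproductive
    development classes, the gonad index, length-binned sex ratios, the
    postovulatory-follicle (POF) method for daily spawning fraction and
    spawning interval, gravimetric batch fecundity from ovary-lobe
    subsamples, small-sample AICc model selection over binomial and Gaussian
    mixed-effects models with cubic-spline terms and a random fishing-set
    intercept, and integration of batch fecundity and spawning fraction into
    potential annual fecundity by length and age. A synthetic
    fish-population generator with known truth supports estimator validation
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    lme4,
    splines,
    stats,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
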