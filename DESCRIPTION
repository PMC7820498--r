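Package: thermoresil
Title: Seasonal Resilience Phenotypes for Dairy Sheep Milk Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives seasonal milk-performance resilience phenotypes for dairy
    sheep from test-day records and weather data, and estimates their genetic
    parameters. Reaction norms are fitted as second-degree Legendre random
    regressions of test-day milk yield on air temperature (or a
    temperature-humidity index), separately by calendar season of lambing;
    individual resilience phenotypes are the slopes of the fitted animal
    curves at stated cold and hot temperatures. Heritabilities and genetic and
    phenotypic correlations of the slope phenotypes and lifetime milk yield
    are estimated with pedigree-based animal-model REML using an
    average-information algorithm and a sparse inverse numerator relationship
    matrix. A synthetic-data generator emulating a Mediterranean dairy sheep
    recording scheme (multi-generation pedigree, seasonal lambing, monthly
    test days, sinusoidal-plus-AR(1) weather) supports end-to-end validation
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    Matrix,
    stats,
    utils,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
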