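Package: stemvib
Title: Free-Vibration Phenotyping of Plant Stems from High-Speed Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of free vibrations of cantilevered plant stems from
    high-speed video. Tracks a red marker on a black background to a
    displacement time series, estimates the damped natural frequency by
    Hanning-windowed FFT and the logarithmic decrement by a four-peak
    log-linear regression selection rule, and derives spring-mass-damper
    mechanical properties (damping ratio, natural frequency, damping
    coefficient, stiffness) from the equivalent-mass model of a uniform
    cantilever. Includes a mutant-screening classifier based on a
    wild-type multiple regression of frequency on growth traits with a
    normal fit to its residuals, plus synthetic trace, video and
    population generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
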