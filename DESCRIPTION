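Package: gazecone
Title: Cone-Width Analysis of Audiovisual Ventriloquism Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-alternative (left/middle/right)
    sound-localization experiments in which a central visual stimulus pulls
    perceived sound locations toward it (the ventriloquism effect). The
    package estimates, per participant and visual condition, the "cone
    width" - the range of azimuths perceived as central - by jointly
    fitting opposed logistic response functions with a derivative-free
    simplex optimizer and locating their intersections with the implied
    middle-response curve. It applies vigilance, edge-accuracy and
    fit-failure exclusion rules, tests condition effects on cone width
    with random-intercept linear mixed models compared by likelihood-ratio
    tests, and ships a synthetic-observer generator with known ground
    truth for parameter-recovery and error-rate calibration studies.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
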