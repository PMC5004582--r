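Package: osmounf
Title: Ultrasensitive Negative Feedback Control of Yeast Osmoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing feedback control of the yeast high-osmolarity
    glycerol (HOG) response. Implements a biophysical osmoshock model of cell
    volume, turgor pressure and glycerol balance closed by two parallel
    feedback branches (the Fps1 glycerol channel and Hog1-mediated glycerol
    production), each of which can carry proportional, integral,
    finite-window integral or ultrasensitive (Hill-type) negative feedback.
    Provides a generic first-order closed-loop testbed linking ultrasensitive
    negative feedback to quasi sliding mode control (boundary layer, gain
    conditions), a synthetic osmoshock dataset generator, least-squares
    fitting of controller schemes by a hybrid genetic algorithm with local
    simplex refinement, and model ranking by AIC, BIC and FPE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
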