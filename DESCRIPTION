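Package: hemopulse
Title: Closed-Loop Lumped-Parameter Hemodynamics with Extra-Aortic
    Counterpulsation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop zero-dimensional (lumped-parameter) simulator of
    the left heart and systemic arterial tree, built for studying soft
    robotic extra-aortic counterpulsation in heart failure with preserved
    ejection fraction. The left atrium and ventricle are time-varying
    elastance chambers with separate passive and active pressure
    components; the mitral and aortic valves are pressure-actuated with a
    continuous opening state; the aorta and its branches are Poiseuille
    resistances terminated by RCR Windkessel beds; and the counterpulsation
    device is an experimentally parameterized pressure source coupled
    through a capacitance into the ascending aorta. Staged calibration
    tunes the vascular and cardiac parameters to a printed patient target
    table, and sweep experiments quantify the hemodynamic effect of
    actuation timing and pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
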