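Package: regrowr
Title: Tumor Regrowth Dynamics and Simulated Recurrence Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates population-level cancer recurrence (Kaplan-Meier-style
    event-free curves) from distributions of post-treatment residual viable
    tumor burden. A continuous regrowth model attenuated by a minimum
    viability threshold (an Allee-type extinction threshold) maps each
    sampled patient burden to cure or a recurrence time at a detection
    threshold, under exponential, logistic or Gompertz growth laws. Includes
    cohort sampling, parameter-effect sweeps, two-arm trial comparison,
    replicate confidence bands, and calibration of the regrowth parameters
    to observed event-free curves by replicate simulation and derivative-free
    loss minimisation.
License: MIT
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
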