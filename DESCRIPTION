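Package: adiposwitch
Title: Bistable Feedback-Loop Modeling of Preadipocyte-to-Adipocyte Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of an ordinary-differential-equation model
    of adipocyte differentiation in which three consecutive positive feedback
    loops (PPARg with C/EBPa, PPARg with C/EBPb, and PPARg with the insulin
    receptor) form a bistable, hysteretic commitment switch, while insulin
    signaling controls lipid accumulation in a graded fashion. Provides
    stimulus-protocol builders, deterministic and stochastic (cell-to-cell
    lognormal parameter variability) population simulation, Gaussian-mixture
    bimodality classification, fixed-point and hysteresis analysis, Hill
    dose-response fitting, a calibration routine for reference parameter sets,
    and a synthetic immunofluorescence image generator with the matching
    single-cell segmentation and quantification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    mclust,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    pracma,
    EBImage,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
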